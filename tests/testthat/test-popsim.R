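test_that("meiosis has the Haldane crossover and Poisson mutation rates", {
  g <- genome_spec() # 1 Morgan, 1e8 bp, mu 1e-8 -> 1 mutation/gamete
  set.seed(1)
  n <- 2000
  muts <- vapply(seq_len(n), function(i)
    length(meiosis(integer(0), integer(0), g)), numeric(1))
  expect_equal(mean(muts), 1.0, tolerance = 0.08) # Poisson(mu * G) = 1

  # crossover rate: one parent strand carries a dense marker grid, the
  # other is empty, so every crossover flips gamete membership of a run of
  # grid markers; the flip count estimates the crossover count
  g0 <- genome_spec(mutation_rate = 0)
  grid <- seq(0L, 99999999L, by = 10000L)
  xovers <- vapply(seq_len(n), function(i) {
    gam <- meiosis(grid, integer(0), g0)
    inc <- grid %in% gam
    sum(inc[-1] != inc[-length(inc)])
  }, numeric(1))
  expect_equal(mean(xovers), 1.0, tolerance = 0.1) # Poisson(map length) = 1
})

test_that("meiosis limits: no mutation and degenerate map copy a parent", {
  g0 <- genome_spec(map_length = 1, mutation_rate = 0)
  h1 <- c(5L, 100L, 5000L); h2 <- c(7L, 900L)
  set.seed(2)
  for (i in 1:20) {
    gam <- meiosis(h1, h2, g0)
    expect_true(all(gam %in% c(h1, h2)))
    expect_false(is.unsorted(gam, strictly = TRUE))
  }
  # zero-length genome: exact copy of one strand
  gz <- genome_spec(map_length = 0, bp_per_cM = 1, mutation_rate = 0)
  gam <- meiosis(h1, h2, gz)
  expect_true(identical(gam, h1) || identical(gam, h2))
})

test_that("haplotypes stay strictly sorted through generations of meiosis", {
  g <- small_genome()
  set.seed(3)
  h1 <- sort(sample.int(5e6, 50L)); h2 <- sort(sample.int(5e6, 60L))
  for (i in 1:50) {
    gam <- meiosis(h1, h2, g, avoid = union(h1, h2))
    expect_false(is.unsorted(gam, strictly = TRUE))
    h2 <- h1; h1 <- gam
  }
})

test_that("base population: config validation and the mutation-free limit", {
  g <- small_genome()
  expect_error(run_base_population(g, ne = 7, generations = 5), "even")
  expect_error(run_base_population(g, ne = 0, generations = 5), "even")
  g_mu0 <- genome_spec(map_length = 2, bp_per_cM = 25000, mutation_rate = 0)
  set.seed(4)
  p <- run_base_population(g_mu0, ne = 20, generations = 30)
  expect_equal(length(unlist(p$haplotypes)), 0L) # no mutation, no variants
})

test_that("equilibrium diversity matches the diffusion expectation", {
  # theta = 4 Ne mu G = 100 for the small genome; expected total pairwise
  # diversity (sum over sites of 2pq, sample-corrected) equals theta.
  base <- small_base()
  vt <- variant_table(base)
  n_chr <- 2 * base$n
  pi_hat <- sum(2 * vt$freq_base * (1 - vt$freq_base)) * n_chr / (n_chr - 1)
  expect_gt(pi_hat, 100 * 0.6)
  expect_lt(pi_hat, 100 * 1.6)
})

test_that("allele frequencies are a martingale under pure drift", {
  base <- small_base()
  vt <- variant_table(base)
  sel <- vt$maf > 0.1 # intermediate sites: measurable drift, low noise
  pos <- vt$position[sel]
  p0 <- vt$freq_base[sel]
  g_mu0 <- genome_spec(map_length = 2, bp_per_cM = 25000, mutation_rate = 0)
  base0 <- wf_population("base", base$haplotypes, base$generation, g_mu0)
  set.seed(5)
  deltas <- replicate(60, {
    nxt <- split_and_propagate(
      base0, split_design(0, 1, ne = ne_small, census_a = ne_small,
                          census_b = ne_small, reference_size = 0,
                          validation_size = 0))$A
    H <- hap_matrix(nxt, pos)
    mean(colMeans(H) - p0)
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3.5 * se + 1e-8)
})

test_that("variants are lost monotonically when mutation is off", {
  base <- small_base()
  g_mu0 <- genome_spec(map_length = 2, bp_per_cM = 25000, mutation_rate = 0)
  pop <- wf_population("base", base$haplotypes, 0, g_mu0)
  set.seed(6)
  n_seg <- integer(0)
  for (i in 1:25) {
    pop <- split_and_propagate(
      pop, split_design(0, 1, ne = ne_small, census_a = ne_small,
                        census_b = ne_small, reference_size = 0,
                        validation_size = 0))$A
    n_seg <- c(n_seg, nrow(variant_table(pop)))
  }
  expect_true(all(diff(n_seg) <= 0))
})

test_that("population split: T = 0 yields identical frequencies, and FST
           grows with divergence time as pure drift predicts", {
  base <- small_base()
  d0 <- split_design(0, 0, ne = ne_small, census_a = ne_small,
                     census_b = ne_small, reference_size = 0,
                     validation_size = 0)
  set.seed(7)
  pops0 <- split_and_propagate(base, d0)
  vt0 <- variant_table(pops0$A, pops0$B)
  expect_equal(vt0$freq_A, vt0$freq_B)

  # E[(pA - pB)^2] = 2 p0 q0 (1 - exp(-T / (2 Ne)))
  fst_hat <- function(t_div, seed) {
    set.seed(seed)
    d <- split_design(0, t_div, ne = ne_small, census_a = ne_small,
                      census_b = ne_small, reference_size = 0,
                      validation_size = 0)
    pops <- split_and_propagate(base, d)
    vtb <- variant_table(base)
    sel <- vtb$maf > 0.1
    pos <- vtb$position[sel]; p0 <- vtb$freq_base[sel]
    pA <- colMeans(hap_matrix(pops$A, pos))
    pB <- colMeans(hap_matrix(pops$B, pos))
    mean((pA - pB)^2) / mean(2 * p0 * (1 - p0))
  }
  f5 <- mean(vapply(1:4, function(s) fst_hat(5L, 70 + s), numeric(1)))
  f25 <- mean(vapply(1:4, function(s) fst_hat(25L, 80 + s), numeric(1)))
  expect_lt(f5, f25) # divergence accumulates
  expect_gt(f5, 0.015); expect_lt(f5, 0.13)   # expected 0.049
  expect_gt(f25, 0.10); expect_lt(f25, 0.40)  # expected 0.221
})

test_that("variant_table prunes sites fixed in all populations and filters
           by pooled MAF", {
  g <- small_genome()
  mk <- function(label, haps) wf_population(label, haps, 0, g)
  # site 10 fixed in both, site 20 fixed in A only, site 30 segregating
  A <- mk("A", list(c(10L, 20L), c(10L, 20L), c(10L, 20L, 30L), c(10L, 20L)))
  B <- mk("B", list(c(10L), c(10L, 30L), c(10L), c(10L, 30L)))
  vt <- variant_table(A, B)
  expect_equal(vt$position, c(20L, 30L))
  expect_equal(vt$freq_A[vt$position == 20], 1)
  expect_equal(vt$freq_B[vt$position == 20], 0)
  expect_equal(vt$freq_pooled[vt$position == 30], 3 / 8)
  vt2 <- variant_table(A, B, min_maf = 0.4)
  expect_equal(vt2$position, 20L) # pooled MAF of site 30 is 3/8 < 0.4
})

test_that("reference/validation partition is disjoint, exhaustive and
           reproducible", {
  g <- small_genome()
  pop <- wf_population("A", replicate(20, integer(0), simplify = FALSE), 0, g)
  set.seed(11)
  pt <- partition_reference_validation(pop, reference_size = 4,
                                       validation_size = 6)
  expect_length(intersect(pt$reference, pt$validation), 0)
  expect_length(pt$reference, 4)
  expect_length(pt$validation, 6)
  set.seed(11)
  pt2 <- partition_reference_validation(pop, reference_size = 4,
                                        validation_size = 6)
  expect_identical(pt, pt2)
  expect_error(partition_reference_validation(pop, reference_size = 8,
                                              validation_size = 6),
               "too small")
  pt0 <- partition_reference_validation(pop, reference_size = 0,
                                        validation_size = 10)
  expect_length(pt0$reference, 0)
})
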