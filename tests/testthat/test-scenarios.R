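# Small-world end-to-end tests of the evaluation designs.  The genome and
# population are scaled far below the default design so a full replicate
# runs in well under a second.

small_design <- function(divergence = 8L, census_a = 120L,
                         reference_size = 40L, validation_size = 60L) {
  split_design(burn_in_generations = 150L,
               divergence_generations = divergence,
               ne = 40L, census_a = census_a, census_b = 120L,
               reference_size = reference_size,
               validation_size = validation_size)
}

test_that("the accuracy scaling parameter is T h2 / (M L)", {
  expect_equal(scaling_lambda(6000, 0.3, 400, 30), 0.15)
  expect_equal(scaling_lambda(200, 0.3, 400, 1), 0.15)
  expect_equal(scaling_lambda(200, 0, 400, 1), 0)
  expect_equal(scaling_lambda(400, 0.3, 400, 1),
               2 * scaling_lambda(200, 0.3, 400, 1))
})

test_that("a simulated replicate is reproducible from its master seed and
           shares genotypes across heritabilities", {
  g <- small_genome()
  st1 <- simulate_replicate(small_design(), g, seed = 77, min_maf = 0.02)
  st2 <- simulate_replicate(small_design(), g, seed = 77, min_maf = 0.02)
  expect_identical(st1$A$haplotypes, st2$A$haplotypes)
  expect_identical(st1$vt, st2$vt)
  expect_identical(st1$valA, st2$valA)
  ts1 <- trait_state(st1, 10, panel_sizes = 50)
  ts2 <- trait_state(st2, 10, panel_sizes = 50)
  # same genotypes, QTL and noise stream: only h2 rescales the phenotypes
  expect_identical(ts1$g, ts2$g)
  expect_identical(ts1$panels$data50$positions, ts2$panels$data50$positions)
})

test_that("all four scenario wirings run end-to-end and score plausible
           accuracies", {
  g <- small_genome()
  set.seed(61)
  st <- simulate_replicate(small_design(census_a = 160L), g, seed = 5,
                           min_maf = 0.02, max_reference = 80L)
  ts <- trait_state(st, 10, panel_sizes = 50)
  for (sc in 1:4) {
    for (m in c("snp_blup", "mixp")) {
      ev <- evaluate_scenario(ts, sc, "wgs", m, 0.30)
      expect_true(is.finite(ev$accuracy))
      expect_gte(ev$accuracy, -1); expect_lte(ev$accuracy, 1)
      expect_equal(ev$n_markers + ev$n_dropped, nrow(st$vt))
    }
  }
  expect_error(evaluate_scenario(ts, 1, "nope", "snp_blup", 0.30),
               "unknown panel")
})

test_that("scenario 4 requires a replicate that carries the enlarged
           reference", {
  g <- small_genome()
  st <- simulate_replicate(small_design(), g, seed = 9)
  ts <- trait_state(st, 10, panel_sizes = 50)
  expect_error(evaluate_scenario(ts, 4, "wgs", "snp_blup", 0.3),
               "max_reference")
})

test_that("zero divergence leaves the two populations with identical
           genotype frequencies", {
  g <- small_genome()
  # with no post-split propagation the census stays at Ne
  d0 <- split_design(150L, 0L, ne = 40L, census_a = 40L, census_b = 40L,
                     reference_size = 10L, validation_size = 20L)
  st <- simulate_replicate(d0, g, seed = 13)
  expect_equal(st$vt$freq_A, st$vt$freq_B)
})

test_that("fitting the reference predicts the reference better than
           held-out individuals (overfitting sanity)", {
  g <- small_genome()
  diff_acc <- vapply(1:5, function(s) {
    st <- simulate_replicate(small_design(), g, seed = 300 + s)
    ts <- trait_state(st, 10, panel_sizes = 50)
    ref <- st$refA[[1]]
    G_ref <- ts$dosages$A$wgs[ref, ]
    G_val <- ts$dosages$A$wgs[st$valA, ]
    rs <- reference_standardization(G_ref, G_val)
    tr <- trait_spec(0.30, var_g = ts$var_g$A)
    y <- simulate_phenotypes(ts$g$A[ref], tr, e_std = ts$e_std$A[ref])
    fit <- fit_snp_blup(y, rs$X_ref, var(ts$g$A[ref]) / ncol(rs$X_ref),
                        tr$sigma_e2)
    acc_in <- prediction_accuracy(ts$g$A[ref], predict_gebv(rs$X_ref, fit))
    acc_out <- prediction_accuracy(ts$g$A[st$valA],
                                   predict_gebv(rs$X_val, fit))
    acc_in - acc_out
  }, numeric(1))
  expect_gt(mean(diff_acc), 0)
})

test_that("run_replicate executes one configuration from scratch", {
  cfg <- scenario_config(1, divergence = 8, n_qtl = 10, h2 = 0.30,
                         panel = "wgs", method = "snp_blup",
                         total_generations = 120, ne = 40)
  out <- run_replicate(cfg, seed = 99, genome = small_genome())
  expect_true(is.finite(out$accuracy))
  expect_s3_class(out$fit, "fit_result")
  expect_equal(out$rep$design$divergence_generations, 8L)
})

test_that("the replication engine shares simulations across the grid and
           summarizes with SE = SD/sqrt(n)", {
  grid <- rbind(
    scenario_config(1, 8, 10, 0.30, "wgs", "snp_blup",
                    total_generations = 120, ne = 40),
    scenario_config(1, 8, 10, 0.07, "wgs", "snp_blup",
                    total_generations = 120, ne = 40),
    scenario_config(1, 8, 10, 0.30, "data50", "snp_blup",
                    total_generations = 120, ne = 40))
  res <- run_replication_design(grid, n_reps = 3, master_seed = 555,
                                genome = small_genome(),
                                total_generations = 120, ne = 40,
                                panel_sizes = 50)
  expect_equal(nrow(res), 9)
  # same simulated populations across h2 and panels within a replicate
  nv <- attr(res, "replicates")
  expect_equal(nrow(nv), 3)
  wgs_markers <- res$n_markers[res$panel == "wgs"]
  expect_equal(wgs_markers[res$h2[res$panel == "wgs"] == 0.30],
               wgs_markers[res$h2[res$panel == "wgs"] == 0.07])
  # rerun with the same master seed: bit-identical genotype state
  res2 <- run_replication_design(grid, n_reps = 3, master_seed = 555,
                                 genome = small_genome(),
                                 total_generations = 120, ne = 40,
                                 panel_sizes = 50)
  expect_identical(res$accuracy, res2$accuracy)

  s <- summarize_replicates(res)
  expect_equal(nrow(s), 3)
  expect_true(all(s$se >= 0))
  expect_equal(s$pct_decrease_vs_wgs[s$panel == "wgs"], c(0, 0))
  # percent decrease computed from unrounded means
  i50 <- s$panel == "data50" & s$h2 == 0.30
  iw <- s$panel == "wgs" & s$h2 == 0.30
  expect_equal(s$pct_decrease_vs_wgs[i50],
               (1 - s$mean_accuracy[i50] / s$mean_accuracy[iw]) * 100)
})

test_that("summary edge cases: single replicate and identical accuracies", {
  res <- data.frame(scenario = 1L, divergence = 8L, n_qtl = 10L, h2 = 0.3,
                    panel = "wgs", method = "snp_blup", rep = 1L,
                    accuracy = 0.5, n_markers = 100L)
  s1 <- summarize_replicates(res)
  expect_true(is.na(s1$se))
  res3 <- do.call(rbind, replicate(3, res, simplify = FALSE))
  res3$rep <- 1:3
  s3 <- summarize_replicates(res3)
  expect_equal(s3$se, 0)
  expect_equal(s3$n_reps, 3)
})
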