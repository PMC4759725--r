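#' @title Wright-Fisher population objects
#' @description A `wf_population` holds the phased haplotypes of a set of
#'   diploid individuals.  Haplotypes are sparse: each is the sorted integer
#'   vector of 0-based bp positions carrying the derived allele "1".
#'   Individual `i` owns haplotypes `2i - 1` and `2i`; the first half of the
#'   individuals are sires, the second half dams.
#' @param label Population label, e.g. `"base"`, `"A"`, `"B"`.
#' @param haplotypes List of sorted integer vectors, two per individual.
#' @param generation Generation index of this sample.
#' @param genome The [genome_spec()] the haplotypes live on.
#' @return An object of class `wf_population`.
#' @export
wf_population <- function(label, haplotypes, generation, genome) {
  stopifnot(length(haplotypes) %% 2 == 0, inherits(genome, "genome_spec"))
  structure(
    list(label = label, haplotypes = haplotypes,
         n = length(haplotypes) %/% 2L,
         generation = generation, genome = genome),
    class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf(
    "wf_population '%s': %d individuals at generation %d, %d segregating sites\n",
    x$label, x$n, x$generation,
    length(unique(unlist(x$haplotypes, use.names = FALSE)))))
  invisible(x)
}

#' One meiosis
#'
#' Forms a gamete from the two haplotypes of a parent: the crossover count
#' is Poisson with mean equal to the map length in Morgan (Haldane model,
#' no interference), crossover positions are uniform on the chromosome, the
#' starting strand is chosen with probability 1/2, and new mutations are
#' added at a Poisson(`mutation_rate * phys_length`) number of previously
#' unoccupied positions (infinite-sites convention).
#'
#' Uses the current R RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param h1,h2 The parent's two haplotypes (sorted integer positions).
#' @param genome A [genome_spec()].
#' @param avoid Integer positions that new mutations must avoid (typically
#'   the population's segregating sites).
#' @return A sorted integer vector: the gamete's derived-allele positions.
#' @export
#' @examples
#' g <- genome_spec()
#' set.seed(1)
#' gam <- meiosis(c(10L, 500L), c(250L, 99999L), g)
meiosis <- function(h1, h2, genome, avoid = integer(0)) {
  cpp_meiosis(as.integer(h1), as.integer(h2),
              genome$map_length, genome$phys_length, genome$mutation_rate,
              draw_seed(), as.integer(avoid))
}

# Founders carry no variation: mutation-drift balance builds it up during
# the burn-in.
empty_founders <- function(ne) {
  replicate(2L * ne, integer(0), simplify = FALSE)
}

#' Simulate the ancestral (base) population
#'
#' Runs an idealized Wright-Fisher population of `ne` diploids (`ne/2`
#' sires, `ne/2` dams) forward for the stated number of non-overlapping
#' generations, starting from mutation-free founders.  Each offspring draws
#' a sire and a dam uniformly with replacement and receives one meiotic
#' gamete from each; mutation and drift are the only evolutionary forces.
#' Sites lost from the population, and sites fixed in it, are pruned.
#'
#' @param genome A [genome_spec()].
#' @param ne Even number of breeding individuals (default 200).
#' @param generations Number of generations to simulate.
#' @return A [wf_population()] labelled `"base"`.
#' @export
run_base_population <- function(genome, ne = 200, generations) {
  if (ne <= 0 || ne %% 2 != 0)
    stop("ne must be a positive even number", call. = FALSE)
  stopifnot(generations >= 0)
  haps <- cpp_propagate(empty_founders(ne), as.integer(generations),
                        as.integer(ne),
                        genome$map_length, genome$phys_length,
                        genome$mutation_rate, draw_seed(),
                        prune_fixed = TRUE, prune_every = 20L)
  wf_population("base", haps, generations, genome)
}

#' Split the base population and propagate two descendant populations
#'
#' The base population is split into populations A and B, each of which is
#' propagated independently (within-population mating only) for
#' `design$divergence_generations` generations at `design$ne`; mutations
#' arising after the split are private to their population.  In the final
#' generation each census is expanded to `design$census_a` / `census_b`
#' offspring by the same random-mating rule.  Sites fixed in one population
#' are retained while they still segregate (or are absent) in the other;
#' joint pruning of sites fixed in both happens in [variant_table()].
#'
#' Both descendant populations start from the same base gene pool: the
#' founders of A and of B are drawn as offspring of the base generation.
#'
#' @param base A [wf_population()] at the burn-in generation.
#' @param design A [split_design()].
#' @return A list with elements `A` and `B`, both [wf_population()]s at the
#'   final generation.
#' @export
split_and_propagate <- function(base, design) {
  stopifnot(inherits(base, "wf_population"), inherits(design, "split_design"))
  g <- base$genome
  td <- design$divergence_generations
  gen_final <- base$generation + td
  prop1 <- function(label, census) {
    haps <- cpp_propagate(base$haplotypes, as.integer(td),
                          as.integer(census),
                          g$map_length, g$phys_length, g$mutation_rate,
                          draw_seed(), prune_fixed = FALSE,
                          prune_every = 20L)
    wf_population(label, haps, gen_final, g)
  }
  list(A = prop1("A", design$census_a), B = prop1("B", design$census_b))
}

#' Random reference / validation partition
#'
#' Draws disjoint random subsets of individuals: `reference_size` with
#' phenotypes for marker-effect estimation and `validation_size` whose
#' breeding values are predicted from genotypes only.
#'
#' @param pop A [wf_population()].
#' @param design A [split_design()] (its `reference_size` and
#'   `validation_size` are used), or `NULL` to pass sizes directly.
#' @param reference_size,validation_size Overrides for the subset sizes.
#' @return A list with integer vectors `reference` and `validation` of
#'   individual indices.
#' @export
partition_reference_validation <- function(pop, design = NULL,
                                           reference_size = design$reference_size,
                                           validation_size = design$validation_size) {
  n <- pop$n
  if (reference_size + validation_size > n)
    stop(sprintf("census %d too small for reference %d + validation %d",
                 n, reference_size, validation_size), call. = FALSE)
  ids <- sample.int(n, reference_size + validation_size)
  list(reference = sort(ids[seq_len(reference_size)]),
       validation = sort(ids[reference_size + seq_len(validation_size)]))
}

#' Table of segregating variants across populations
#'
#' Collects the union of derived-allele positions over one or more
#' populations and computes per-population derived-allele frequencies, the
#' pooled frequency (weighting populations by chromosome count) and the
#' pooled minor-allele frequency.  Sites fixed (frequency 0 or 1) in every
#' population simultaneously are excluded, and an optional MAF filter can
#' be applied.
#'
#' @param ... One or more [wf_population()]s.
#' @param min_maf Retain only sites with pooled minor-allele frequency
#'   strictly greater than this (default 0, i.e. all polymorphic sites).
#' @return A data frame with columns `position`, one `freq_<label>` per
#'   population, `freq_pooled` and `maf`, sorted by position.
#' @export
variant_table <- function(..., min_maf = 0) {
  pops <- list(...)
  if (length(pops) == 1L && !inherits(pops[[1L]], "wf_population"))
    pops <- pops[[1L]]
  stopifnot(length(pops) >= 1L,
            all(vapply(pops, inherits, logical(1), "wf_population")))
  labels <- vapply(pops, function(p) p$label, character(1))
  pos <- sort(unique(unlist(lapply(pops, function(p)
    unlist(p$haplotypes, use.names = FALSE)), use.names = FALSE)))
  counts <- lapply(pops, function(p) {
    tabulate(match(unlist(p$haplotypes, use.names = FALSE), pos),
             nbins = length(pos))
  })
  nchr <- vapply(pops, function(p) 2L * p$n, integer(1))
  freqs <- Map(function(cnt, n) cnt / n, counts, nchr)
  pooled <- Reduce(`+`, counts) / sum(nchr)
  # drop sites carrying no variation anywhere: the derived allele absent
  # from, or fixed in, every population for the same state (sites fixed for
  # opposite alleles in two populations still vary across populations)
  fixed_all <- Reduce(`&`, lapply(freqs, function(f) f == 0)) |
    Reduce(`&`, lapply(freqs, function(f) f == 1))
  maf <- pmin(pooled, 1 - pooled)
  keep <- !fixed_all & maf > min_maf
  out <- data.frame(position = pos[keep])
  for (i in seq_along(pops))
    out[[paste0("freq_", labels[i])]] <- freqs[[i]][keep]
  out$freq_pooled <- pooled[keep]
  out$maf <- maf[keep]
  out
}

#' Phased haplotype matrix at a set of marker positions
#'
#' @param pop A [wf_population()].
#' @param positions Sorted integer marker positions.
#' @return An integer 0/1 matrix of dimension `2 * n_individuals` x
#'   `length(positions)`; rows `2i - 1` and `2i` are individual `i`'s
#'   haplotypes.
#' @export
hap_matrix <- function(pop, positions) {
  cpp_hap_matrix(pop$haplotypes, as.integer(positions))
}

#' Genotype dosage matrix at a set of marker positions
#'
#' @inheritParams hap_matrix
#' @return An integer matrix (`n_individuals` x markers) counting copies of
#'   the derived allele "1" (0, 1 or 2).
#' @export
dosage_matrix <- function(pop, positions) {
  h <- hap_matrix(pop, positions)
  odd <- seq(1L, nrow(h), by = 2L)
  h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
}
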