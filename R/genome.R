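#' Genome specification
#'
#' Describes the simulated chromosome: its genetic map length, the physical
#' to genetic distance ratio, and the per-base mutation rate.  Under the
#' defaults the chromosome spans 1 Morgan at 1 Mb/cM, i.e. 1e8 bp, and each
#' gamete receives on average one crossover and one new mutation per meiosis.
#'
#' @param map_length Genetic length in Morgan (default 1).
#' @param bp_per_cM Physical base pairs per centiMorgan (default 1e6).
#' @param mutation_rate Per-bp, per-meiosis mutation probability
#'   (default 1e-8).
#'
#' @return An object of class `genome_spec` with fields `map_length`,
#'   `bp_per_cM`, `mutation_rate` and the derived `phys_length` in bp.
#' @export
#' @examples
#' g <- genome_spec()
#' g$phys_length # 1e8 bp
genome_spec <- function(map_length = 1, bp_per_cM = 1e6,
                        mutation_rate = 1e-8) {
  stopifnot(map_length >= 0, bp_per_cM > 0,
            mutation_rate >= 0, mutation_rate < 1)
  structure(
    list(map_length = map_length,
         bp_per_cM = bp_per_cM,
         mutation_rate = mutation_rate,
         phys_length = map_length * 100 * bp_per_cM),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %g Morgan, %g bp (%g bp/cM), mu = %g/bp/meiosis\n",
              x$map_length, x$phys_length, x$bp_per_cM, x$mutation_rate))
  invisible(x)
}

#' Population split and sampling design
#'
#' Describes the demographic design: the burn-in length of the ancestral
#' population, the number of generations `divergence` the two descendant
#' populations evolve independently, the census each population is expanded
#' to in its final generation, and the sizes of the reference (phenotyped)
#' and validation (genotype-only) samples drawn from that census.
#'
#' In the default design, a population of Ne = 200 runs for 1950 or 1990
#' generations, splits into populations A and B which each propagate for 50
#' or 10 further generations (2000 in total), and each census is expanded to
#' 500 individuals of which 200 form the reference and 300 the validation
#' set.  When a 400-individual reference is required, the census of A is
#' raised to 700 so the validation set stays at 300.
#'
#' @param burn_in_generations Generations before the split (default 1950).
#' @param divergence_generations Generations after the split, `T` (default
#'   50).
#' @param ne Effective (breeding) population size per population; must be
#'   even (default 200).
#' @param census_a,census_b Final census sizes of populations A and B
#'   (default 500 each).
#' @param reference_size Individuals with phenotypes (default 200).
#' @param validation_size Individuals predicted from genotypes only
#'   (default 300).
#'
#' @return An object of class `split_design`.
#' @export
split_design <- function(burn_in_generations = 1950,
                         divergence_generations = 50,
                         ne = 200,
                         census_a = 500, census_b = 500,
                         reference_size = 200, validation_size = 300) {
  stopifnot(burn_in_generations >= 0, divergence_generations >= 0,
            ne >= 4, ne %% 2 == 0, census_a >= 2, census_b >= 2,
            reference_size >= 0, validation_size >= 0)
  if (reference_size + validation_size > census_a)
    stop("reference_size + validation_size exceeds census_a", call. = FALSE)
  structure(
    list(burn_in_generations = burn_in_generations,
         divergence_generations = divergence_generations,
         ne = ne, census_a = census_a, census_b = census_b,
         reference_size = reference_size,
         validation_size = validation_size),
    class = "split_design")
}

#' @export
print.split_design <- function(x, ...) {
  cat(sprintf(
    "split_design: %d burn-in + %d divergence generations, Ne = %d,\n",
    x$burn_in_generations, x$divergence_generations, x$ne))
  cat(sprintf("  census A/B = %d/%d, reference %d, validation %d\n",
              x$census_a, x$census_b, x$reference_size, x$validation_size))
  invisible(x)
}
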