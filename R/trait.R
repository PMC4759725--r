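#' Sample causative QTL and assign standardized allelic effects
#'
#' Draws `n_qtl` loci uniformly without replacement from a variant table
#' (already restricted to the MAF class of interest), assigns each a raw
#' allelic effect for the derived allele "1" from a standard normal
#' distribution, and standardizes the effects against the supplied allele
#' frequencies so the total additive genetic variance equals 1 (see
#' [standardize_effects()]).
#'
#' @param vt A variant table from [variant_table()].
#' @param n_qtl Number of QTL (45 or 132 in the default designs).
#' @param freq_col Name of the frequency column used for standardization
#'   (default `"freq_A"`: the focal population's frequencies).
#' @return An object of class `qtl_set`: a data frame with columns
#'   `position`, `p` (standardization frequency), `a_raw` and `a`.
#' @export
sample_qtl <- function(vt, n_qtl, freq_col = "freq_A") {
  if (n_qtl > nrow(vt))
    stop(sprintf("n_qtl = %d exceeds the %d available loci", n_qtl, nrow(vt)),
         call. = FALSE)
  if (!freq_col %in% names(vt))
    stop("freq_col '", freq_col, "' not found in variant table", call. = FALSE)
  idx <- sort(sample.int(nrow(vt), n_qtl))
  qtl <- data.frame(position = vt$position[idx], p = vt[[freq_col]][idx])
  qtl$a_raw <- rnorm(n_qtl)
  qtl$a <- if (n_qtl > 0) standardize_effects(qtl$a_raw, qtl$p) else numeric(0)
  class(qtl) <- c("qtl_set", "data.frame")
  qtl
}

#' Standardize QTL allelic effects to unit genetic variance
#'
#' Rescales raw allelic effects `a'` so that the additive genetic variance
#' implied by the allele frequencies `p`, assuming linkage equilibrium,
#' equals 1:
#' `a_j = a'_j / sqrt(sum_k 2 p_k (1 - p_k) (a'_k)^2)`.
#'
#' @param a_raw Raw allelic effects.
#' @param p Derived-allele frequencies at the same loci.
#' @return Standardized effects satisfying `sum(2 p (1-p) a^2) == 1`.
#' @export
#' @examples
#' a <- standardize_effects(3, 0.5)
#' 2 * 0.5 * 0.5 * a^2 # 1
standardize_effects <- function(a_raw, p) {
  stopifnot(length(a_raw) == length(p))
  v <- sum(2 * p * (1 - p) * a_raw^2)
  if (!is.finite(v) || v <= 0)
    stop("degenerate genetic variance: all effects zero or all QTL fixed",
         call. = FALSE)
  a_raw / sqrt(v)
}

#' True additive genetic values
#'
#' `g_i = sum_j x_ij a_j`, where `x_ij` counts copies of allele "1" that
#' individual `i` carries at QTL `j`.
#'
#' @param dosages Integer matrix (individuals x QTL) of allele-"1" counts.
#' @param a Standardized allelic effects, one per QTL column.
#' @return Numeric vector of genetic values, one per individual.
#' @export
genetic_values <- function(dosages, a) {
  if (ncol(dosages) != length(a))
    stop("dosage columns and effects differ in length", call. = FALSE)
  drop(dosages %*% a)
}

#' Trait specification at a target heritability
#'
#' Fixes the environmental variance so the trait has heritability `h2`
#' against a genetic variance `var_g`:
#' `sigma_e^2 = var_g * (1 - h2) / h2`.  Calibrating against the realized
#' `var(g)` of a population sample makes the heritability hold in that
#' sample.
#'
#' @param h2 Narrow-sense heritability in (0, 1].
#' @param var_g Genetic variance to calibrate against (default 1, the
#'   simulated target).
#' @return An object of class `trait_spec` with fields `h2`, `var_g`,
#'   `sigma_e2`.
#' @export
#' @examples
#' trait_spec(0.30)$sigma_e2 # 7/3
trait_spec <- function(h2, var_g = 1) {
  if (!is.finite(h2) || h2 <= 0 || h2 > 1)
    stop("h2 must lie in (0, 1]", call. = FALSE)
  stopifnot(var_g >= 0)
  structure(list(h2 = h2, var_g = var_g,
                 sigma_e2 = var_g * (1 - h2) / h2),
            class = "trait_spec")
}

#' Simulate phenotypes around true genetic values
#'
#' `y_i = g_i + e_i` with `e_i ~ N(0, sigma_e^2)`.  Supplying `e_std`
#' (standard-normal draws, one per individual) reuses one environmental
#' stream across heritabilities: the same genotypes and environmental ranks
#' yield traits at different h2 by rescaling, which is how replicates are
#' shared between heritability levels.
#'
#' @param g True genetic values.
#' @param trait A [trait_spec()].
#' @param e_std Optional standard-normal vector of `length(g)`; drawn from
#'   the current RNG stream when `NULL`.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotypes <- function(g, trait, e_std = NULL) {
  stopifnot(inherits(trait, "trait_spec"))
  if (is.null(e_std)) e_std <- rnorm(length(g))
  stopifnot(length(e_std) == length(g))
  g + sqrt(trait$sigma_e2) * e_std
}
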