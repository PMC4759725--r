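#' Signed linkage disequilibrium r between two loci
#'
#' Computed from phased haplotypes: `r = D / sqrt(p_i q_i p_j q_j)` with
#' `D = p_11 - p_i p_j`, where frequencies refer to the derived allele "1"
#' at each locus, so the sign is anchored to the fixed allele coding.
#'
#' @param H 0/1 haplotype matrix (haplotypes x loci), e.g. from
#'   [hap_matrix()].
#' @param i,j Column indices of the two loci.
#' @return Signed r in `[-1, 1]`.
#' @export
signed_r <- function(H, i, j) {
  pi_ <- mean(H[, i]); pj <- mean(H[, j])
  if (pi_ %in% c(0, 1) || pj %in% c(0, 1))
    stop("signed r is undefined at a monomorphic locus", call. = FALSE)
  p11 <- mean(H[, i] * H[, j])
  (p11 - pi_ * pj) / sqrt(pi_ * (1 - pi_) * pj * (1 - pj))
}

# Signed r for every adjacent column pair; NA where a locus is monomorphic.
adjacent_signed_r <- function(H) {
  m <- ncol(H)
  if (m < 2L) return(numeric(0))
  p <- colMeans(H)
  p11 <- colMeans(H[, -m, drop = FALSE] * H[, -1L, drop = FALSE])
  pl <- p[-m]; pr <- p[-1L]
  den <- sqrt(pl * (1 - pl) * pr * (1 - pr))
  r <- (p11 - pl * pr) / den
  r[den == 0] <- NA_real_
  r
}

bin_table <- function(dist_bp, values, bin_kb, stat_fun, min_n = 1L) {
  bin <- floor(dist_bp / (bin_kb * 1000))
  keep <- !is.na(values)
  bins <- sort(unique(bin[keep]))
  out <- data.frame(
    bin_start_kb = bins * bin_kb,
    bin_end_kb = (bins + 1) * bin_kb,
    statistic = vapply(bins, function(b) {
      v <- values[keep & bin == b]
      if (length(v) < min_n) NA_real_ else stat_fun(v)
    }, numeric(1)),
    n_pairs = vapply(bins, function(b) sum(keep & bin == b), integer(1)))
  out
}

#' Within-population LD decay over adjacent marker pairs
#'
#' Squared correlation (r^2) between adjacent markers of a panel, computed
#' from phased haplotypes and averaged in distance bins.  Pairs involving a
#' locus monomorphic in the population are skipped.
#'
#' @param pop A [wf_population()].
#' @param panel A [marker_panel()] (markers sorted by position).
#' @param bin_kb Bin width for the pair distance, in kb (default 50).
#' @return Data frame `bin_start_kb`, `bin_end_kb`, `statistic` (mean r^2),
#'   `n_pairs`.  Bins without pairs are absent, not zero.
#' @export
adjacent_ld_curve <- function(pop, panel, bin_kb = 50) {
  H <- hap_matrix(pop, panel$positions)
  r <- adjacent_signed_r(H)
  bin_table(diff(panel$positions), r^2, bin_kb, mean)
}

#' Persistency of LD phase between two populations
#'
#' For each adjacent marker pair of a panel, the signed r is computed in
#' each population; within each distance bin the persistency is the
#' correlation across pairs of the two populations' signed r values.
#' Pairs with a locus monomorphic in either population are excluded.
#' Persistency is symmetric in the two population labels.
#'
#' @param pop_a,pop_b Two [wf_population()]s.
#' @inheritParams adjacent_ld_curve
#' @return Data frame `bin_start_kb`, `bin_end_kb`, `statistic` (per-bin
#'   correlation of signed r), `n_pairs`; bins with fewer than two usable
#'   pairs report `NA`.
#' @export
persistency_curve <- function(pop_a, pop_b, panel, bin_kb = 50) {
  ra <- adjacent_signed_r(hap_matrix(pop_a, panel$positions))
  rb <- adjacent_signed_r(hap_matrix(pop_b, panel$positions))
  ok <- !is.na(ra) & !is.na(rb)
  dist_bp <- diff(panel$positions)
  bin <- floor(dist_bp / (bin_kb * 1000))
  bins <- sort(unique(bin[ok]))
  data.frame(
    bin_start_kb = bins * bin_kb,
    bin_end_kb = (bins + 1) * bin_kb,
    statistic = vapply(bins, function(b) {
      sel <- ok & bin == b
      if (sum(sel) < 2L || sd(ra[sel]) == 0 || sd(rb[sel]) == 0)
        return(NA_real_)
      cor(ra[sel], rb[sel])
    }, numeric(1)),
    n_pairs = vapply(bins, function(b) sum(ok & bin == b), integer(1)))
}
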