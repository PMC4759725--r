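#' Marker panel
#'
#' An ordered set of marker positions used as predictors: either the full
#' whole-genome-sequence (WGS) set, which includes the causative QTL, or a
#' subsampled SNP panel from which QTL are excluded.
#'
#' @param name Panel name (`"wgs"`, `"data3000"`, ..., or custom).
#' @param positions Sorted integer marker positions.
#' @param includes_qtl Whether causative QTL are among the markers.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(name, positions, includes_qtl = FALSE) {
  stopifnot(!is.unsorted(positions, strictly = TRUE))
  structure(list(name = name, positions = as.integer(positions),
                 includes_qtl = includes_qtl),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel '%s': %d markers%s\n", x$name,
              length(x$positions),
              if (x$includes_qtl) " (QTL included)" else ""))
  invisible(x)
}

#' Build the WGS panel and subsampled SNP panels
#'
#' The WGS panel contains every MAF-passing variant, QTL included.  Each
#' SNP panel of the requested sizes is drawn uniformly without replacement
#' from the non-QTL loci, independently of the other panels (panels are not
#' nested).
#'
#' @param vt Variant table restricted to the MAF class of interest.
#' @param qtl A [sample_qtl()] result (its positions are excluded from the
#'   SNP panels).
#' @param sizes Integer panel sizes (default `c(3000, 2000, 1000, 200)`).
#' @return Named list of [marker_panel()]s: `wgs` plus one `data<size>` per
#'   requested size.
#' @export
build_panels <- function(vt, qtl, sizes = c(3000, 2000, 1000, 200)) {
  non_qtl <- setdiff(vt$position, qtl$position)
  if (length(sizes) && max(sizes) > length(non_qtl))
    stop(sprintf("largest panel size %d exceeds the %d non-QTL loci",
                 max(sizes), length(non_qtl)), call. = FALSE)
  panels <- list(wgs = marker_panel("wgs", vt$position, includes_qtl = TRUE))
  for (s in sizes) {
    nm <- paste0("data", s)
    panels[[nm]] <- marker_panel(nm, sort(sample(non_qtl, s)))
  }
  panels
}

#' Standardize genotype dosages
#'
#' Maps allele-"1" dosages 0/1/2 at a locus with allele frequency `p` to
#' `-2p / sqrt(2pq)`, `(1 - 2p) / sqrt(2pq)` and `2(1 - p) / sqrt(2pq)`
#' (`q = 1 - p`), so that columns have mean zero over the sample whose
#' frequencies define `p`.  The same `p` must be used to standardize
#' reference and validation genotypes.
#'
#' @param dosages Integer matrix (individuals x markers) of 0/1/2 dosages.
#' @param p Allele-"1" frequencies, one per column, each strictly inside
#'   (0, 1); drop monomorphic columns before calling (see
#'   [reference_standardization()]).
#' @return Numeric matrix of standardized genotypes.
#' @export
standardize_genotypes <- function(dosages, p) {
  stopifnot(ncol(dosages) == length(p))
  if (any(p <= 0 | p >= 1))
    stop("allele frequencies must lie strictly in (0, 1); ",
         "drop monomorphic columns first", call. = FALSE)
  sweep(sweep(dosages, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), `/`)
}

#' Reference-based standardization of reference and validation genotypes
#'
#' Computes allele frequencies from the reference dosages (the individuals
#' the model is fitted on, since validation individuals carry genotypes
#' only), drops markers monomorphic in the reference, and standardizes both
#' matrices with the same frequencies.
#'
#' @param geno_ref Reference dosage matrix (individuals x markers).
#' @param geno_val Validation dosage matrix over the same markers (may be
#'   `NULL`).
#' @return List with `X_ref`, `X_val`, `p` (frequencies of the retained
#'   markers), `keep` (logical over the input columns) and `n_dropped`.
#' @export
reference_standardization <- function(geno_ref, geno_val = NULL) {
  p <- colMeans(geno_ref) / 2
  keep <- p > 0 & p < 1
  pk <- p[keep]
  list(X_ref = standardize_genotypes(geno_ref[, keep, drop = FALSE], pk),
       X_val = if (!is.null(geno_val))
         standardize_genotypes(geno_val[, keep, drop = FALSE], pk),
       p = pk, keep = keep, n_dropped = sum(!keep))
}

#' Mean adjacent inter-marker distance of a panel
#'
#' @param panel A [marker_panel()] or an integer vector of positions.
#' @return Mean adjacent spacing in kb.
#' @export
mean_inter_marker_distance <- function(panel) {
  pos <- if (inherits(panel, "marker_panel")) panel$positions else panel
  if (length(pos) < 2L)
    stop("at least two markers are required", call. = FALSE)
  mean(diff(sort(pos))) / 1000
}
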