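#' Export phased genotypes as a (sites-only) VCF file
#'
#' Writes the individuals of a population at the markers of a panel as an
#' uncompressed VCF v4.2 with phased diploid GT fields, so external LD and
#' genotype tools can cross-check the internal statistics.  The derived
#' allele "1" is written as ALT `A`, the ancestral as REF `G` (placeholder
#' bases: the simulator tracks positions, not sequence).
#'
#' @param pop A [wf_population()].
#' @param panel A [marker_panel()].
#' @param file Output path.
#' @param chrom Chromosome name (default `"1"`).
#' @return Invisibly, the file path.
#' @export
write_vcf <- function(pop, panel, file, chrom = "1") {
  H <- hap_matrix(pop, panel$positions)
  ids <- paste0(pop$label, seq_len(pop$n))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       as.integer(pop$genome$phys_length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  odd <- seq(1L, nrow(H), by = 2L)
  for (j in seq_along(panel$positions)) {
    gt <- paste0(H[odd, j], "|", H[odd + 1L, j])
    writeLines(paste(c(chrom, panel$positions[j] + 1L,
                       paste0("snp", panel$positions[j]), "G", "A", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(file)
}

#' Export genotypes as PLINK ped/map text files
#'
#' Map distances are reported in cM (`bp / bp_per_cM`); alleles are coded
#' `A` (derived, "1") and `G` (ancestral, "0").
#'
#' @inheritParams write_vcf
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(pop, panel, prefix, chrom = "1") {
  pos <- panel$positions
  map <- data.frame(chrom = chrom, id = paste0("snp", pos),
                    cm = pos / pop$genome$bp_per_cM, bp = pos + 1L)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  H <- hap_matrix(pop, pos)
  allele <- c("G", "A")
  odd <- seq(1L, nrow(H), by = 2L)
  n <- pop$n
  sex <- rep(c(1L, 2L), c(ceiling(n / 2), floor(n / 2)))
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    geno <- paste(allele[H[odd[i], ] + 1L], allele[H[odd[i] + 1L, ] + 1L])
    writeLines(paste(c(pop$label, paste0(pop$label, i), 0L, 0L, sex[i], -9L,
                       geno), collapse = " "), con)
  }
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' @importFrom utils write.table
NULL
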