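#' Published summary tables for the global B. carinata GBS panel
#'
#' Small reference tables reported for the published worldwide
#' *Brassica carinata* genotyping-by-sequencing diversity panel (620
#' accessions, 10,199 filtered SNPs): per-chromosome SNP counts, the
#' STRUCTURE subpopulation assignment counts at the Q >= 0.70 threshold,
#' and the genomic coordinates of the candidate selection regions. The
#' underlying genotype data are not redistributable, but these printed
#' summaries are useful as arithmetic inputs — e.g. subgenome SNP
#' shares, assignment percentages, region spans, and the marker-count
#' calculation via [min_markers_for_gwas()] (genome size 1,284,000 to
#' 1,544,000 kb; whole-genome LD decay 700 kb).
#'
#' @param table one of `"snp_counts"`, `"structure_counts"`, `"roi"`.
#' @return A data.frame.
#' @export
carinata_reported <- function(table = c("snp_counts", "structure_counts",
                                        "roi")) {
  table <- match.arg(table)
  f <- c(snp_counts = "carinata_chrom_snp_counts.tsv",
         structure_counts = "carinata_structure_counts.tsv",
         roi = "carinata_roi.tsv")[[table]]
  path <- system.file("extdata", f, package = "gbspopgen")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
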