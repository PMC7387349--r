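#' Classify SNP sites by genomic context
#'
#' Assigns each variant a `context` of `coding` (inside any CDS segment),
#' `intron` (inside a gene model but in none of its exons), or
#' `intergenic`. Where overlapping gene models disagree the most specific
#' class wins (coding > intron > intergenic). Sites inside non-coding
#' exon sequence (UTRs, when the annotation distinguishes exons from CDS)
#' fall back to `intergenic`-style treatment only if outside every gene;
#' inside a gene they are reported as `coding` when in CDS, otherwise
#' `intron` only when outside all exons.
#'
#' @param vt a [variant_table()].
#' @param ann a [genome_annotation()].
#' @return The variant table with its `context` column filled.
#' @export
annotate_sites <- function(vt, ann) {
  missing_chrom <- setdiff(unique(vt$chrom), names(ann$seq))
  if (length(missing_chrom))
    stop("chromosome(s) absent from annotation: ",
         paste(missing_chrom, collapse = ", "))
  snp <- GenomicRanges::GRanges(vt$chrom, IRanges::IRanges(vt$pos, vt$pos))
  as_gr <- function(df) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end))
  in_cds <- IRanges::overlapsAny(snp, as_gr(ann$cds))
  in_exon <- IRanges::overlapsAny(snp, as_gr(ann$exons))
  in_gene <- IRanges::overlapsAny(snp, as_gr(ann$genes))
  ctx <- rep("intergenic", nrow(vt))
  ctx[in_gene & !in_exon] <- "intron"
  ctx[in_cds] <- "coding"
  vt$context <- ctx
  vt
}

# Locate the CDS segment containing a position for one gene; returns the
# codon (transcript strand), the offset of the site within it, and the
# transcript-strand REF/ALT bases.
codon_at <- function(pos, ref, alt, gene_cds, chrom_seq) {
  strand <- gene_cds$strand[1]
  tx <- gene_cds[order(gene_cds$start), , drop = FALSE]
  if (strand == "-") tx <- tx[rev(seq_len(nrow(tx))), , drop = FALSE]
  seg_len <- tx$end - tx$start + 1L
  cum <- cumsum(c(0L, seg_len))
  seg <- which(pos >= tx$start & pos <= tx$end)
  if (length(seg) != 1L) return(NULL)
  within <- if (strand == "+") pos - tx$start[seg] else tx$end[seg] - pos
  cds_pos <- cum[seg] + within  # 0-based position in spliced CDS
  # honour the first segment's phase (bases preceding the first full codon)
  lead <- if (!is.null(tx$phase)) tx$phase[1] else 0L
  if (cds_pos < lead) return(NULL)
  codon_idx <- (cds_pos - lead) %/% 3L
  offset <- (cds_pos - lead) %% 3L
  # genomic coordinates of the three codon bases, transcript order
  codon_cds_pos <- lead + codon_idx * 3L + 0:2
  if (codon_cds_pos[3] >= cum[length(cum)]) return(NULL)
  genome_pos <- integer(3)
  for (i in 1:3) {
    cp <- codon_cds_pos[i]
    s <- findInterval(cp, cum, rightmost.closed = FALSE)
    w <- cp - cum[s]
    genome_pos[i] <- if (strand == "+") tx$start[s] + w else tx$end[s] - w
  }
  bases <- as.character(Biostrings::extractAt(
    chrom_seq, IRanges::IRanges(genome_pos, genome_pos)))
  if (strand == "-")
    bases <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(bases)))
  comp <- function(b) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(b)))
  list(codon = paste(bases, collapse = ""), offset = offset,
       ref_tx = if (strand == "+") ref else comp(ref),
       alt_tx = if (strand == "+") alt else comp(alt))
}

#' Classify coding SNPs as synonymous or non-synonymous
#'
#' For every variant with `context == "coding"`, substitutes the ALT base
#' into its codon (strand-aware, reading frame from the CDS phase) and
#' translates with the standard genetic code. A premature stop counts as
#' non-synonymous. Other variants keep `effect = NA`.
#'
#' @param vt an annotated [variant_table()] (run [annotate_sites()] first).
#' @param ann a [genome_annotation()].
#' @return The variant table with its `effect` column filled.
#' @export
classify_coding_effect <- function(vt, ann) {
  if (all(is.na(vt$context)))
    stop("variant table has no context annotation; run annotate_sites()")
  code <- Biostrings::GENETIC_CODE
  effect <- rep(NA_character_, nrow(vt))
  coding <- which(vt$context == "coding")
  cds_by_chrom <- split(ann$cds, ann$cds$chrom)
  for (i in coding) {
    ch <- vt$chrom[i]; pos <- vt$pos[i]
    cds <- cds_by_chrom[[ch]]
    hit <- cds[cds$start <= pos & cds$end >= pos, , drop = FALSE]
    if (!nrow(hit)) next
    gene_cds <- ann$cds[ann$cds$gene_id == hit$gene_id[1], , drop = FALSE]
    info <- codon_at(pos, vt$ref[i], vt$alt[i], gene_cds, ann$seq[[ch]])
    if (is.null(info)) next
    ref_codon <- strsplit(info$codon, NULL)[[1]]
    if (ref_codon[info$offset + 1L] != info$ref_tx)
      stop("REF allele disagrees with reference sequence at ",
           ch, ":", pos)
    alt_codon <- ref_codon
    alt_codon[info$offset + 1L] <- info$alt_tx
    aa_ref <- code[[paste(ref_codon, collapse = "")]]
    aa_alt <- code[[paste(alt_codon, collapse = "")]]
    effect[i] <- if (identical(aa_ref, aa_alt)) "synonymous" else "non-synonymous"
  }
  vt$effect <- effect
  vt
}

#' Genes overlapping a set of regions
#'
#' Interval query of the gene models against arbitrary regions (e.g.
#' regions of interest from a sweep scan, or large haplotype blocks),
#' reporting each overlapping gene with the length of the intersection.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed) and optionally `region_id`.
#' @param ann a [genome_annotation()].
#' @return data.frame with one row per (region, gene) overlap: region_id,
#'   chrom, region start/end, gene_id, gene start/end, overlap_bp.
#' @export
genes_in_regions <- function(regions, ann) {
  if (is.null(regions$region_id))
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom,
                                 regions$start, regions$end)
  empty <- data.frame(region_id = character(), chrom = character(),
                      region_start = integer(), region_end = integer(),
                      gene_id = character(), gene_start = integer(),
                      gene_end = integer(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(regions)) return(empty)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(ann$genes$chrom,
                               IRanges::IRanges(ann$genes$start,
                                                ann$genes$end))
  ov <- GenomicRanges::findOverlaps(rg, gg)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  overlap <- pmin(regions$end[qi], ann$genes$end[si]) -
    pmax(regions$start[qi], ann$genes$start[si]) + 1L
  data.frame(region_id = regions$region_id[qi], chrom = regions$chrom[qi],
             region_start = regions$start[qi], region_end = regions$end[qi],
             gene_id = ann$genes$gene_id[si],
             gene_start = ann$genes$start[si],
             gene_end = ann$genes$end[si],
             overlap_bp = as.integer(overlap), stringsAsFactors = FALSE)
}
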