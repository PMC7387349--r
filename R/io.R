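#' Read a VCF into a genotype matrix and variant table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeping only biallelic SNP
#' records with a diploid GT field. Dosage is the count of ALT alleles;
#' `./.` becomes a missing call. Per-call depth is taken from the DP
#' FORMAT field when present; records without DP get unknown depth
#' (`NA`), which downstream depth filtering skips.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return A list with elements `genotypes` ([geno_matrix()]), `variants`
#'   ([variant_table()]), and `n_skipped` (records dropped as
#'   multi-allelic or non-SNP).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  is_snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  n_skipped <- sum(!is_snp)
  if (!any(is_snp)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  fmt_has_dp <- any(grepl("DP", v@gt[, 1], fixed = TRUE))
  if (fmt_has_dp) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[is_snp, , drop = FALSE]
    depth <- matrix(as.integer(dp), nrow(dp), ncol(dp), dimnames = dimnames(dp))
  } else {
    depth <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  depth[is.na(dosage) & !is.na(depth) & depth > 0] <- 0L
  vt <- variant_table(fix[is_snp, "CHROM"], as.integer(fix[is_snp, "POS"]),
                      fix[is_snp, "REF"], fix[is_snp, "ALT"])
  gm <- geno_matrix(t(dosage), t(depth))
  vt <- refresh_variant_stats(vt, gm)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s) in ", basename(path))
  list(genotypes = gm, variants = vt, n_skipped = n_skipped)
}

# Structural pre-check so malformed files fail with a line number instead
# of an opaque parser error: every data line must have a constant column
# count matching the header.
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) stop("missing #CHROM header line in ", path)
  n_col <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr + 1L, length.out = length(lines) - hdr)
  if (length(body) == 0L) stop("zero usable records in ", path)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(nf != n_col)
  if (length(bad))
    stop("malformed VCF line ", body[bad[1]], " in ", path, ": expected ",
         n_col, " fields, found ", nf[bad[1]])
  invisible(TRUE)
}

#' Write a genotype matrix as VCF 4.2 (GT:DP)
#'
#' @param gm a [geno_matrix()].
#' @param vt the matching [variant_table()].
#' @param path output file path.
#' @param contig_lengths optional named vector of chromosome lengths for
#'   the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, vt, path, contig_lengths = NULL) {
  d <- gm$dosage; dp <- gm$depth
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  obs <- !is.na(d)
  gt[obs] <- gt_code[d[obs] + 1L]
  dp_chr <- matrix(".", nrow(d), ncol(d))
  dp_chr[!is.na(dp)] <- as.character(dp[!is.na(dp)])
  cell <- matrix(paste(gt, dp_chr, sep = ":"), nrow(d), ncol(d))
  body_fields <- apply(cell, 2L, paste, collapse = "\t")
  fixed <- paste(vt$chrom, vt$pos, vt$snp_name, vt$ref, vt$alt, ".", "PASS",
                 ".", "GT:DP", sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=gbspopgen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">')
  if (!is.null(contig_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths),
                                as.integer(contig_lengths)))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", rownames(d)),
                            collapse = "\t"))
  writeLines(c(header, paste(fixed, body_fields, sep = "\t")), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based closed coordinates)
#' for a [genome_annotation()].
#'
#' @param ann a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  lines <- c("##gff-version 3")
  gene_lines <- sprintf("%s\tgbspopgen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$chrom, g$start, g$end, g$strand, g$gene_id)
  mrna_lines <- sprintf("%s\tgbspopgen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                        g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id)
  e <- ann$exons
  exon_lines <- sprintf("%s\tgbspopgen\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                        e$chrom, e$start, e$end, e$strand, e$gene_id)
  cd <- ann$cds
  cds_lines <- sprintf("%s\tgbspopgen\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.t1",
                       cd$chrom, cd$start, cd$end, cd$strand, cd$phase,
                       cd$gene_id)
  ord <- order(c(g$chrom, g$chrom, e$chrom, cd$chrom),
               c(g$start, g$start, e$start, cd$start),
               c(rep(1L, nrow(g)), rep(2L, nrow(g)),
                 rep(3L, nrow(e)), rep(4L, nrow(cd))))
  writeLines(c(lines, c(gene_lines, mrna_lines, exon_lines, cds_lines)[ord]),
             path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads gene and CDS features (with phase) from a GFF3 file into the flat
#' tables used by [genome_annotation()]. Sequences must be supplied
#' separately (FASTA).
#'
#' @param gff_path path to a GFF3 file.
#' @param fasta_path path to the matching FASTA reference.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff_path, fasta_path) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  raw <- utils::read.table(gff_path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("chrom", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attr"))
  get_attr <- function(attr, key) {
    m <- regexpr(paste0(key, "=[^;]+"), attr)
    out <- rep(NA_character_, length(attr))
    out[m > 0] <- sub(paste0("^", key, "="), "", regmatches(attr, m))
    out
  }
  gn <- raw[raw$type == "gene", ]
  genes <- data.frame(gene_id = get_attr(gn$attr, "ID"), chrom = gn$chrom,
                      start = gn$start, end = gn$end, strand = gn$strand,
                      stringsAsFactors = FALSE)
  cd <- raw[raw$type == "CDS", ]
  cds <- data.frame(gene_id = sub("\\.t1$", "", get_attr(cd$attr, "Parent")),
                    chrom = cd$chrom, start = cd$start, end = cd$end,
                    strand = cd$strand, phase = as.integer(cd$phase),
                    stringsAsFactors = FALSE)
  ex <- raw[raw$type == "exon", ]
  exons <- if (nrow(ex)) {
    data.frame(gene_id = sub("\\.t1$", "", get_attr(ex$attr, "Parent")),
               chrom = ex$chrom, start = ex$start, end = ex$end,
               strand = ex$strand, stringsAsFactors = FALSE)
  } else NULL
  genome_annotation(seq, genes, cds, exons)
}

#' Export a panel bundle to standard files
#'
#' Writes `panel.vcf` (GT:DP), `genes.gff3`, `reference.fa`,
#' `truth_pops.tsv` and (when sweeps were planted) `truth_sweeps.tsv`
#' into a directory. The VCF round-trips losslessly through [read_vcf()]
#' for both GT and DP.
#'
#' @param panel a [panel_bundle()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
export_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             gff = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "reference.fa"),
             pops = file.path(dir, "truth_pops.tsv"))
  cl <- NULL
  if (!is.null(panel$annotation))
    cl <- stats::setNames(Biostrings::width(panel$annotation$seq),
                          names(panel$annotation$seq))
  write_vcf(panel$genotypes, panel$variants, paths["vcf"], cl)
  if (!is.null(panel$annotation)) {
    write_gff3(panel$annotation, paths["gff"])
    Biostrings::writeXStringSet(panel$annotation$seq, paths["fasta"])
  }
  utils::write.table(panel$truth$pops, paths["pops"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(panel$truth$sweeps)) {
    paths["sweeps"] <- file.path(dir, "truth_sweeps.tsv")
    utils::write.table(panel$truth$sweeps, paths["sweeps"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
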