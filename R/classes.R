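#' Genotype matrix container
#'
#' Holds a samples x loci matrix of alternate-allele dosages (0, 1, 2, or
#' `NA` for a missing call) together with a matching matrix of per-call
#' sequencing depths. Depth is `NA` where the source VCF carried no DP
#' field; missing genotype calls have depth 0 (or `NA` if unknown).
#'
#' @param dosage integer matrix, samples in rows, loci in columns; values
#'   in `{0, 1, 2, NA}`. Row names are sample identifiers, column names
#'   SNP names.
#' @param depth integer matrix of the same dimensions, non-negative; `NA`
#'   where depth is unknown.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, depth = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(depth)) {
    depth <- matrix(NA_integer_, nrow(dosage), ncol(dosage),
                    dimnames = dimnames(dosage))
  }
  depth <- as.matrix(depth)
  if (!all(dim(dosage) == dim(depth)))
    stop("dosage and depth matrices must have identical dimensions")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  if (any(!is.na(depth) & depth < 0))
    stop("depths must be non-negative")
  storage.mode(dosage) <- "integer"
  storage.mode(depth) <- "integer"
  structure(list(dosage = dosage, depth = depth,
                 sample_ids = rownames(dosage)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosage
  miss <- mean(is.na(d))
  cat(sprintf("geno_matrix: %d samples x %d loci (%.1f%% missing calls)\n",
              nrow(d), ncol(d), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i sample index (rows).
#' @param j locus index (columns).
#' @param ... ignored.
#' @return A `geno_matrix` restricted to the requested samples/loci.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  geno_matrix(x$dosage[i, j, drop = FALSE], x$depth[i, j, drop = FALSE])
}

#' Build a variant table
#'
#' Per-locus metadata: chromosome, 1-based position, REF/ALT alleles, the
#' SNP name (`<chrom>_<pos>` by convention), summary frequencies, and the
#' annotation columns `context` (coding / intron / intergenic) and
#' `effect` (synonymous / non-synonymous, `NA` outside coding sequence).
#'
#' @param chrom character chromosome identifiers.
#' @param pos integer 1-based positions, strictly increasing within each
#'   chromosome.
#' @param ref,alt single-base alleles.
#' @param snp_name optional names; default `<chrom>_<pos>`.
#' @return A `data.frame` with class `variant_table` prepended.
#' @export
variant_table <- function(chrom, pos, ref, alt, snp_name = NULL) {
  pos <- as.integer(pos)
  if (is.null(snp_name)) snp_name <- paste(chrom, pos, sep = "_")
  vt <- data.frame(chrom = as.character(chrom), pos = pos,
                   ref = as.character(ref), alt = as.character(alt),
                   snp_name = snp_name,
                   maf = NA_real_, het_rate = NA_real_,
                   missing_rate = NA_real_,
                   context = NA_character_, effect = NA_character_,
                   stringsAsFactors = FALSE)
  for (ch in unique(vt$chrom)) {
    p <- vt$pos[vt$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Genome annotation container
#'
#' Chromosome sequences plus gene models. Gene models are flat tables
#' (one row per feature interval) rather than nested objects: `genes` has
#' one row per gene, `cds` one row per CDS segment with its reading-frame
#' phase, `exons` one row per exon. Coordinates are 1-based closed.
#'
#' @param seq a [Biostrings::DNAStringSet] named by chromosome.
#' @param genes data.frame with columns gene_id, chrom, start, end, strand.
#' @param cds data.frame with columns gene_id, chrom, start, end, strand,
#'   phase (0/1/2: bases to skip before the first complete codon).
#' @param exons data.frame with columns gene_id, chrom, start, end, strand;
#'   defaults to `cds` (genes without UTRs).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(seq, genes, cds, exons = NULL) {
  if (is.null(exons)) exons <- cds[, c("gene_id", "chrom", "start", "end", "strand")]
  for (g in unique(cds$gene_id)) {
    len <- sum(cds$end[cds$gene_id == g] - cds$start[cds$gene_id == g] + 1L)
    if (len %% 3L != 0L)
      stop("CDS length of gene ", g, " is not divisible by 3")
  }
  widths <- stats::setNames(Biostrings::width(seq), names(seq))
  chk <- function(df, what) {
    w <- widths[df$chrom]
    if (any(is.na(w)))
      stop(what, " on chromosome absent from the sequence set")
    if (any(df$start < 1L | df$end > w | df$start > df$end))
      stop(what, " interval outside chromosome bounds")
  }
  chk(genes, "gene"); chk(cds, "CDS"); chk(exons, "exon")
  structure(list(seq = seq, genes = genes, cds = cds, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosomes (%.2f Mb), %d genes\n",
              length(x$seq), sum(Biostrings::width(x$seq)) / 1e6,
              nrow(x$genes)))
  invisible(x)
}

#' Bundle a simulated or imported panel
#'
#' @param genotypes a [geno_matrix()].
#' @param variants a [variant_table()].
#' @param annotation a [genome_annotation()] or `NULL`.
#' @param truth list with elements `pops` (data.frame sample_id, pop) and
#'   `sweeps` (data.frame chrom, start, end, target_pop,
#'   haplotype_fraction), or `NULL` for imported panels.
#' @return An object of class `panel_bundle`.
#' @export
panel_bundle <- function(genotypes, variants, annotation = NULL, truth = NULL) {
  if (ncol(genotypes$dosage) != nrow(variants))
    stop("genotype matrix has ", ncol(genotypes$dosage),
         " loci but variant table has ", nrow(variants), " rows")
  if (!is.null(truth) && !is.null(truth$sweeps) && nrow(truth$sweeps) &&
      !is.null(annotation)) {
    w <- stats::setNames(Biostrings::width(annotation$seq), names(annotation$seq))
    s <- truth$sweeps
    if (any(s$start < 1 | s$end > w[s$chrom]))
      stop("planted sweep interval outside chromosome bounds")
  }
  structure(list(genotypes = genotypes, variants = variants,
                 annotation = annotation, truth = truth),
            class = "panel_bundle")
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat(sprintf("panel_bundle: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes$dosage), nrow(x$variants),
              length(unique(x$variants$chrom))))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: pops %s; %d planted sweep(s)\n",
                paste(table(x$truth$pops$pop), collapse = "/"),
                if (is.null(x$truth$sweeps)) 0L else nrow(x$truth$sweeps)))
  }
  invisible(x)
}
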