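# Builders for tiny in-memory fixtures used across the suite.

# geno_matrix from a plain matrix (samples x loci), depth constant.
gm_of <- function(m, depth = 10L) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%03d", seq_len(ncol(m)))
  dp <- matrix(depth, nrow(m), ncol(m), dimnames = dimnames(m))
  dp[is.na(m)] <- 0L
  geno_matrix(m, dp)
}

# variant table on one chromosome at the given positions.
vt_of <- function(pos, chrom = "B1", ref = "A", alt = "G") {
  variant_table(rep(chrom, length(pos)), pos,
                rep(ref, length(pos)), rep(alt, length(pos)))
}

# Single-gene annotation from an explicit chromosome sequence and CDS
# segments; exon intervals default to the CDS.
ann_of <- function(seq_string, cds, genes = NULL, chrom = "B1") {
  seq <- Biostrings::DNAStringSet(stats::setNames(seq_string, chrom))
  if (is.null(genes)) {
    genes <- do.call(rbind, lapply(split(cds, cds$gene_id), function(g)
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 start = min(g$start), end = max(g$end),
                 strand = g$strand[1], stringsAsFactors = FALSE)))
    rownames(genes) <- NULL
  }
  genome_annotation(seq, genes, cds)
}

# CDS table helper.
cds_row <- function(gene_id, start, end, strand = "+", phase = 0L,
                    chrom = "B1") {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, phase = phase, stringsAsFactors = FALSE)
}

# Small two-population Balding-Nichols panel for structure/diversity tests.
small_panel <- function(seed = 1, n_per_pop = c(60, 40), fst = 0.15,
                        n_chrom = 1, chrom_length = 2e6, loci = 200,
                        selfing = 0.8, missing = 0.05, sweeps = list()) {
  simulate_panel(sim_config(n_per_pop = n_per_pop, n_chrom = n_chrom,
                            chrom_length = chrom_length,
                            n_loci_per_chrom = loci, fst_param = fst,
                            selfing_rate = selfing, missing_rate = missing,
                            depth_mean = 10, sweep_specs = sweeps,
                            seed = seed))
}

# Align a 2-column Q matrix so column 2 tracks truth01 (label switching).
align_q2 <- function(Q, truth01) {
  err1 <- mean(abs(Q[, 1] - truth01))
  err2 <- mean(abs(Q[, 2] - truth01))
  if (err1 < err2) Q[, 2:1] else Q
}
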