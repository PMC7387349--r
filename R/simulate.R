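#' Configuration for the synthetic genotype-panel generator
#'
#' Defaults emulate a global GBS collection of an inbreeding allotetraploid
#' crop: 620 diploid lines split 549/41 between two diverged subpopulations
#' across the 17 chromosomes B1-B8 and C1-C9, with Balding-Nichols
#' differentiation matching the observed subpopulation F_ST (0.148), strong
#' inbreeding (F_IS near 0.82 modelled as heterozygote conversion), sparse
#' SNP coverage, 10% missing calls and GBS-scale sequencing depth.
#' Chromosomes are drawn at 10 Mb, a desk-scale stand-in for ~75 Mb
#' Brassica chromosomes that preserves realistic within-window SNP counts.
#'
#' @param n_per_pop diploid samples per subpopulation; length-1 or length-2.
#' @param n_chrom number of chromosomes (named B1..B8 then C1..C9, cycling
#'   beyond 17).
#' @param chrom_length chromosome length in bp.
#' @param n_loci_per_chrom SNP loci per chromosome (>= 2).
#' @param fst_param Balding-Nichols differentiation parameter in [0, 1).
#' @param selfing_rate probability that a heterozygote is collapsed to a
#'   homozygote (models inbreeding phenomenology).
#' @param missing_rate per-call missingness probability.
#' @param depth_mean mean of the zero-truncated Poisson sequencing depth.
#' @param sweep_specs list of [sweep_spec()] objects to plant.
#' @param seed integer; fully determines the generated panel.
#' @param with_annotation generate reference sequence and gene models
#'   (`TRUE`, the default). Disable for large panels used only for
#'   statistics that never touch the sequence.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = c(549L, 41L),
                       n_chrom = 17L,
                       chrom_length = 1e7,
                       n_loci_per_chrom = 600L,
                       fst_param = 0.148,
                       selfing_rate = 0.82,
                       missing_rate = 0.10,
                       depth_mean = 8,
                       sweep_specs = list(),
                       seed = 1L,
                       with_annotation = TRUE) {
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, 2L)
  if (length(n_per_pop) != 2L || any(n_per_pop < 1))
    stop("n_per_pop must give one or two positive sample counts")
  if (fst_param < 0 || fst_param >= 1)
    stop("fst_param must lie in [0, 1)")
  check_prob(selfing_rate, "selfing_rate")
  check_prob(missing_rate, "missing_rate")
  if (n_loci_per_chrom < 2L) stop("n_loci_per_chrom must be >= 2")
  if (chrom_length < 2e5)
    stop("chrom_length must cover at least two 100-kb windows")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  structure(list(n_per_pop = as.integer(n_per_pop),
                 n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 n_loci_per_chrom = as.integer(n_loci_per_chrom),
                 fst_param = fst_param, selfing_rate = selfing_rate,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 sweep_specs = sweep_specs, seed = as.integer(seed),
                 with_annotation = isTRUE(with_annotation)),
            class = "sim_config")
}

#' Specification of a planted selective-sweep region
#'
#' @param chrom chromosome identifier.
#' @param start,end interval in bp, `start < end`.
#' @param target_pop subpopulation index (1 or 2) receiving the founder
#'   haplotype.
#' @param haplotype_fraction fraction in (0, 1] of target-pop samples made
#'   homozygous for the founder haplotype.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, start, end, target_pop = 2L,
                       haplotype_fraction = 0.9) {
  if (start >= end) stop("sweep interval must satisfy start < end")
  if (haplotype_fraction <= 0 || haplotype_fraction > 1)
    stop("haplotype_fraction must lie in (0, 1]")
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), target_pop = as.integer(target_pop),
                 haplotype_fraction = haplotype_fraction),
            class = "sweep_spec")
}

chrom_names <- function(n) {
  base <- c(paste0("B", 1:8), paste0("C", 1:9))
  if (n <= 17L) return(base[seq_len(n)])
  c(base, paste0("X", seq_len(n - 17L)))
}

# Random gene models tiled along a chromosome: three exons (multiples of 3
# bases, CDS only, no UTRs) separated by introns, genes separated by
# intergenic gaps. Interval fractions are tuned so that roughly 45% of
# uniformly placed SNPs fall in CDS, 23% in introns and 32% between genes.
simulate_gene_models <- function(chrom, chrom_length) {
  genes <- list(); cds <- list()
  pos <- 1L + sample.int(2000L, 1L)
  gi <- 0L
  while (TRUE) {
    exon_len <- 3L * sample(200:400, 3L, replace = TRUE)
    intron_len <- sample(400:1000, 2L, replace = TRUE)
    span <- sum(exon_len) + sum(intron_len)
    if (pos + span - 1L > chrom_length - 100L) break
    gi <- gi + 1L
    gene_id <- sprintf("%s_g%04d", chrom, gi)
    strand <- sample(c("+", "-"), 1L)
    starts <- pos + cumsum(c(0L, exon_len[1] + intron_len[1],
                             exon_len[2] + intron_len[2]))
    ends <- starts + exon_len - 1L
    genes[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                              start = pos, end = pos + span - 1L,
                              strand = strand, stringsAsFactors = FALSE)
    # phase per segment in transcription order, rows stored by coordinate
    seg <- data.frame(gene_id = gene_id, chrom = chrom, start = starts,
                      end = ends, strand = strand, phase = NA_integer_,
                      stringsAsFactors = FALSE)
    tx_order <- if (strand == "+") order(seg$start) else order(-seg$start)
    cum_len <- cumsum(c(0L, (seg$end - seg$start + 1L)[tx_order]))[1:3]
    seg$phase[tx_order] <- (3L - cum_len %% 3L) %% 3L
    cds[[gi]] <- seg[order(seg$start), ]
    pos <- pos + span + sample(800:3000, 1L)
  }
  if (gi == 0L)
    return(list(genes = data.frame(gene_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   strand = character()),
                cds = data.frame(gene_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), phase = integer())))
  list(genes = do.call(rbind, genes), cds = do.call(rbind, cds))
}

simulate_annotation <- function(chroms, chrom_length) {
  seqs <- character(length(chroms))
  genes <- list(); cds <- list()
  for (i in seq_along(chroms)) {
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), chrom_length,
                            replace = TRUE), collapse = "")
    gm <- simulate_gene_models(chroms[i], chrom_length)
    genes[[i]] <- gm$genes; cds[[i]] <- gm$cds
  }
  seq <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  genome_annotation(seq, do.call(rbind, genes), do.call(rbind, cds))
}

#' Simulate a two-subpopulation GBS genotype panel
#'
#' Draws a multi-chromosome biallelic SNP panel under the Balding-Nichols
#' model: ancestral allele frequencies are uniform on (0.05, 0.95), the two
#' subpopulation frequencies are Beta-distributed around them with variance
#' governed by `fst_param`, and diploid genotypes are binomial draws that
#' are then pushed toward homozygosity (`selfing_rate`), thinned by missing
#' calls (`missing_rate`) and given zero-truncated Poisson depths. Any
#' sweep regions in `config$sweep_specs` are planted last via
#' [plant_sweep()]. The whole panel is a deterministic function of
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [panel_bundle()] with genotypes, variant table, genome
#'   annotation and truth labels/intervals.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- chrom_names(config$n_chrom)
  n1 <- config$n_per_pop[1]; n2 <- config$n_per_pop[2]
  n <- n1 + n2
  pop <- rep(c("SP1", "SP2"), c(n1, n2))
  sample_ids <- sprintf("S%04d", seq_len(n))
  FST <- config$fst_param
  L_chr <- config$n_loci_per_chrom

  ann <- if (config$with_annotation)
    simulate_annotation(chroms, config$chrom_length) else NULL

  dosage_list <- list(); depth_list <- list(); vt_list <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pos <- sort(sample.int(config$chrom_length, L_chr))
    p_anc <- stats::runif(L_chr, 0.05, 0.95)
    if (FST == 0) {
      p1 <- p_anc; p2 <- p_anc
    } else {
      a <- p_anc * (1 - FST) / FST
      b <- (1 - p_anc) * (1 - FST) / FST
      p1 <- stats::rbeta(L_chr, a, b)
      p2 <- stats::rbeta(L_chr, a, b)
    }
    g1 <- matrix(stats::rbinom(n1 * L_chr, 2L, rep(p1, each = n1)), n1, L_chr)
    g2 <- matrix(stats::rbinom(n2 * L_chr, 2L, rep(p2, each = n2)), n2, L_chr)
    g <- rbind(g1, g2)
    if (config$selfing_rate > 0) {
      het <- which(g == 1L)
      conv <- het[stats::runif(length(het)) < config$selfing_rate]
      g[conv] <- 2L * stats::rbinom(length(conv), 1L, 0.5)
    }
    depth <- matrix(stats::rpois(n * L_chr, config$depth_mean), n, L_chr)
    depth[depth == 0L] <- 1L
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * L_chr) < config$missing_rate, n, L_chr)
      g[miss] <- NA_integer_
      depth[miss] <- 0L
    }
    if (is.null(ann)) {
      ref <- sample(c("A", "C", "G", "T"), L_chr, replace = TRUE)
    } else {
      ref <- strsplit(as.character(Biostrings::extractAt(
        ann$seq[[ch]], IRanges::IRanges(pos, pos))), NULL)
      ref <- vapply(ref, `[`, "", 1L)
    }
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    dosage_list[[ci]] <- g
    depth_list[[ci]] <- depth
    vt_list[[ci]] <- variant_table(rep(ch, L_chr), pos, ref, unname(alt))
  }
  dosage <- do.call(cbind, dosage_list)
  depth <- do.call(cbind, depth_list)
  vt <- do.call(rbind, vt_list)
  class(vt) <- c("variant_table", "data.frame")
  rownames(vt) <- NULL
  dimnames(dosage) <- list(sample_ids, vt$snp_name)
  dimnames(depth) <- dimnames(dosage)
  gm <- geno_matrix(dosage, depth)
  vt <- refresh_variant_stats(vt, gm)
  truth <- list(pops = data.frame(sample_id = sample_ids, pop = pop,
                                  stringsAsFactors = FALSE),
                sweeps = NULL)
  panel <- panel_bundle(gm, vt, ann, truth)
  for (sp in config$sweep_specs) panel <- plant_sweep(panel, sp)
  panel
}

#' Plant a selective-sweep signature into a panel
#'
#' Copies a single founder haplotype (one gamete drawn from the target
#' subpopulation's allele frequencies) homozygously into a fraction of the
#' target-population samples at every locus inside the interval. Missing
#' calls keep their missing status. This depresses nucleotide diversity in
#' the target population, raises local F_ST, and creates long-range LD -
#' the classic footprint of a recent sweep in an inbreeding population.
#'
#' @param panel a [panel_bundle()].
#' @param spec a [sweep_spec()].
#' @param seed optional integer; set when calling outside a seeded
#'   simulation stream.
#' @return The modified `panel_bundle` with the sweep appended to
#'   `truth$sweeps`.
#' @export
plant_sweep <- function(panel, spec, seed = NULL) {
  stopifnot(inherits(panel, "panel_bundle"), inherits(spec, "sweep_spec"))
  if (!is.null(seed)) set.seed(seed)
  vt <- panel$variants
  if (!spec$chrom %in% vt$chrom)
    stop("unknown chromosome in sweep spec: ", spec$chrom)
  loci <- which(vt$chrom == spec$chrom & vt$pos >= spec$start &
                  vt$pos <= spec$end)
  if (length(loci) < 2L)
    stop("sweep interval ", spec$chrom, ":", spec$start, "-", spec$end,
         " contains fewer than 2 loci")
  pops <- panel$truth$pops$pop
  pop_label <- sort(unique(pops))[spec$target_pop]
  if (is.na(pop_label)) stop("target_pop index out of range")
  members <- which(pops == pop_label)
  n_carriers <- max(1L, round(spec$haplotype_fraction * length(members)))
  carriers <- sample(members, n_carriers)
  d <- panel$genotypes$dosage
  p_target <- colMeans(d[members, loci, drop = FALSE], na.rm = TRUE) / 2
  p_target[is.na(p_target)] <-
    colMeans(d[, loci, drop = FALSE], na.rm = TRUE)[is.na(p_target)] / 2
  p_target[is.na(p_target)] <- 0.5
  founder <- stats::rbinom(length(loci), 1L, p_target)
  block <- matrix(rep(2L * founder, each = length(carriers)),
                  nrow = length(carriers))
  keep_na <- is.na(d[carriers, loci, drop = FALSE])
  block[keep_na] <- NA_integer_
  d[carriers, loci] <- block
  panel$genotypes$dosage <- d
  panel$variants <- refresh_variant_stats(panel$variants, panel$genotypes)
  rec <- data.frame(chrom = spec$chrom, start = spec$start, end = spec$end,
                    target_pop = pop_label,
                    haplotype_fraction = spec$haplotype_fraction,
                    stringsAsFactors = FALSE)
  panel$truth$sweeps <- rbind(panel$truth$sweeps, rec)
  panel
}
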