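#' Apply GBS SNP quality filters
#'
#' Standard quality control for a GBS SNP panel, applied in a fixed order:
#' first per-call depth masking (calls with depth below `depth_min` are
#' set missing; calls with unknown depth are left alone), then per-locus
#' removal of sites with minor allele frequency at or below `maf_min`,
#' observed heterozygote fraction above `het_max` (a guard against
#' collapsed paralogs in polyploid-derived genomes), or missing-call
#' fraction above `missing_max`. All locus statistics are recomputed after
#' the depth masking, and each removal rule is counted against the
#' post-masking matrix in the stated order.
#'
#' @param gm a [geno_matrix()].
#' @param vt the matching [variant_table()].
#' @param maf_min loci with MAF \eqn{\le} this are removed (strict
#'   "MAF > maf_min" retention).
#' @param het_max maximum tolerated observed heterozygote fraction
#'   (inclusive).
#' @param depth_min minimum per-call read depth (inclusive); calls below
#'   it are masked missing before the locus tests.
#' @param missing_max maximum tolerated missing fraction (inclusive,
#'   "up to" semantics).
#' @return A list with `genotypes`, `variants` (filtered, stats
#'   refreshed), and `report` — a data.frame counting calls masked and
#'   loci removed per rule.
#' @export
filter_snps <- function(gm, vt, maf_min = 0.05, het_max = 0.1,
                        depth_min = 4, missing_max = 0.30) {
  check_prob(maf_min, "maf_min")
  check_prob(het_max, "het_max")
  check_prob(missing_max, "missing_max")
  if (depth_min < 0) stop("depth_min must be non-negative")
  d <- gm$dosage; dp <- gm$depth
  low_dp <- !is.na(d) & !is.na(dp) & dp < depth_min
  n_masked <- sum(low_dp)
  d[low_dp] <- NA_integer_
  dp[low_dp] <- 0L
  gm2 <- geno_matrix(d, dp)
  ls <- locus_summary(d)
  drop_maf <- !is.na(ls$maf) & ls$maf <= maf_min
  drop_het <- !drop_maf & !is.na(ls$het_rate) & ls$het_rate > het_max
  # all-missing loci land here too (missing_rate = 1)
  drop_miss <- !drop_maf & !drop_het & ls$missing_rate > missing_max
  keep <- !(drop_maf | drop_het | drop_miss)
  report <- data.frame(
    rule = c("depth_masked_calls", "low_maf", "high_heterozygosity",
             "high_missingness", "retained"),
    count = c(n_masked, sum(drop_maf), sum(drop_het), sum(drop_miss),
              sum(keep)))
  gm_out <- gm2[, keep]
  vt_out <- vt[keep, , drop = FALSE]
  class(vt_out) <- c("variant_table", "data.frame")
  vt_out <- refresh_variant_stats(vt_out, gm_out)
  rownames(vt_out) <- NULL
  list(genotypes = gm_out, variants = vt_out, report = report)
}

#' Impute missing genotype calls from allele frequencies
#'
#' Each missing call at locus *l* is drawn as Binomial(2, p_l) with p_l
#' the ALT-allele frequency among the observed calls at that locus.
#' Observed calls are never altered. This keeps allele frequencies
#' unbiased in expectation, which is what the downstream frequency-based
#' statistics require; it does not borrow haplotype information.
#'
#' @param gm a [geno_matrix()] (typically after [filter_snps()]).
#' @param vt the matching [variant_table()] (unused beyond a dimension
#'   check; kept for interface symmetry).
#' @param seed integer seed; imputation is deterministic given it.
#' @return A `geno_matrix` with no missing dosages; imputed calls get the
#'   locus mean depth (rounded) as a nominal depth.
#' @export
impute_missing <- function(gm, vt = NULL, seed = 1L) {
  if (!is.null(vt) && nrow(vt) != ncol(gm$dosage))
    stop("variant table does not match genotype matrix")
  d <- gm$dosage
  miss <- is.na(d)
  if (!any(miss)) return(gm)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0L))
    stop("cannot impute: locus with zero observed calls (e.g. column ",
         which(n_obs == 0L)[1], ")")
  set.seed(seed)
  p <- colMeans(d, na.rm = TRUE) / 2
  idx <- which(miss, arr.ind = TRUE)
  d[miss] <- stats::rbinom(nrow(idx), 2L, p[idx[, 2]])
  dp <- gm$depth
  mean_dp <- round(colMeans(dp, na.rm = TRUE))
  mean_dp[!is.finite(mean_dp)] <- NA_integer_
  dp[miss] <- as.integer(pmax(1L, mean_dp[idx[, 2]]))
  geno_matrix(d, dp)
}
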