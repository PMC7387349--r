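`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a single probability in [0, 1]")
  x
}

#' Derive a stage seed from a master seed
#'
#' Deterministic sub-seed derivation: one user-facing seed fans out to
#' per-stage / per-replicate seeds so pipeline stages can be rerun in
#' isolation. Results stay below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param offset integer stage/replicate offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 10007) %% 2147483629)
}

# Per-locus summaries from a dosage matrix (NA = missing call).
locus_summary <- function(dosage) {
  n_obs <- colSums(!is.na(dosage))
  p_alt <- ifelse(n_obs > 0, colMeans(dosage, na.rm = TRUE) / 2, NA_real_)
  het <- ifelse(n_obs > 0, colMeans(dosage == 1L, na.rm = TRUE), NA_real_)
  list(n_obs = n_obs,
       p_alt = p_alt,
       maf = pmin(p_alt, 1 - p_alt),
       het_rate = het,
       missing_rate = colMeans(is.na(dosage)))
}

# Refresh the summary columns of a variant table from genotypes.
refresh_variant_stats <- function(vt, gm) {
  ls <- locus_summary(gm$dosage)
  vt$maf <- ls$maf
  vt$het_rate <- ls$het_rate
  vt$missing_rate <- ls$missing_rate
  vt
}

stopifnot_samples_match <- function(gm, labels) {
  if (length(labels) != nrow(gm$dosage))
    stop("population labels (", length(labels),
         ") do not match sample count (", nrow(gm$dosage), ")")
}
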