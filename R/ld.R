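#' Pairwise composite r-squared within a physical window
#'
#' Squared dosage correlation (composite, Rogers-Huff style) between all
#' locus pairs on the same chromosome separated by at most `window_bp`,
#' over pairwise-complete samples. Significance is approximated by the
#' one-degree chi-squared statistic \eqn{N r^2} with N the number of
#' complete sample pairs. Pairs where either locus is monomorphic in the
#' complete subset are skipped and counted.
#'
#' @param gm a [geno_matrix()].
#' @param vt matching [variant_table()] (sorted by position).
#' @param window_bp maximum pair separation in bp.
#' @return data.frame of class `ld_pairs`: i, j (locus indices), chrom,
#'   pos_i, pos_j, dist_bp, r2, n, p_value; attribute `n_skipped`.
#' @export
pairwise_r2 <- function(gm, vt, window_bp = 5e5) {
  d <- gm$dosage
  out <- list(); skipped <- 0L
  for (ch in unique(vt$chrom)) {
    sel <- which(vt$chrom == ch)
    pos <- vt$pos[sel]
    m <- length(sel)
    for (a in seq_len(m - 1)) {
      upper <- pos[a] + window_bp
      b <- which(pos > pos[a] & pos <= upper)
      b <- b[b > a]
      if (!length(b)) next
      x <- d[, sel[a]]
      Y <- d[, sel[b], drop = FALSE]
      r <- suppressWarnings(as.vector(
        stats::cor(x, Y, use = "pairwise.complete.obs")))
      n <- colSums(!is.na(x) & !is.na(Y))
      bad <- !is.finite(r)
      skipped <- skipped + sum(bad)
      if (all(bad)) next
      r2 <- r[!bad]^2
      out[[length(out) + 1L]] <- data.frame(
        i = sel[a], j = sel[b][!bad], chrom = ch,
        pos_i = pos[a], pos_j = pos[b][!bad],
        dist_bp = pos[b][!bad] - pos[a],
        r2 = r2, n = n[!bad],
        p_value = stats::pchisq(n[!bad] * r2, df = 1, lower.tail = FALSE))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), chrom = character(),
               pos_i = integer(), pos_j = integer(), dist_bp = integer(),
               r2 = numeric(), n = integer(), p_value = numeric())
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' LD decay curve and decay distance
#'
#' Bins significant pairs (p-value at most `alpha`) by physical distance
#' into left-closed 25-kb bins from zero, and reports the decay distance:
#' the left edge of the first bin, scanning outward, whose mean
#' \eqn{r^2} falls below `r2_threshold`. Panels in near-complete LD
#' never cross the threshold and return an `NA` decay distance.
#'
#' @param pairs output of [pairwise_r2()].
#' @param bin_bp bin width in bp.
#' @param r2_threshold critical \eqn{r^2} (conventionally 0.1).
#' @param alpha significance cutoff for including a pair.
#' @return A list of class `ld_decay`: `bins` (bin_start, bin_mid,
#'   mean_r2, n_pairs), `decay_distance_bp` (NA if never below
#'   threshold), `threshold`, `n_pairs_used`.
#' @export
ld_decay <- function(pairs, bin_bp = 25000, r2_threshold = 0.1,
                     alpha = 0.05) {
  sig <- pairs[pairs$p_value <= alpha, , drop = FALSE]
  if (!nrow(sig)) {
    warning("no significant pairs; decay curve undefined")
    return(structure(list(bins = data.frame(bin_start = integer(),
                                            bin_mid = numeric(),
                                            mean_r2 = numeric(),
                                            n_pairs = integer()),
                          decay_distance_bp = NA_real_,
                          threshold = r2_threshold, n_pairs_used = 0L),
                     class = "ld_decay"))
  }
  bin <- floor(sig$dist_bp / bin_bp)
  n_bins <- max(bin) + 1L
  mean_r2 <- rep(NA_real_, n_bins); n_pairs <- integer(n_bins)
  agg <- tapply(sig$r2, bin, mean)
  cnt <- table(bin)
  mean_r2[as.integer(names(agg)) + 1L] <- agg
  n_pairs[as.integer(names(cnt)) + 1L] <- as.integer(cnt)
  if (any(n_pairs == 0L))
    warning(sum(n_pairs == 0L), " empty distance bin(s) skipped")
  bins <- data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_bp,
                     bin_mid = ((seq_len(n_bins) - 1L) + 0.5) * bin_bp,
                     mean_r2 = mean_r2, n_pairs = n_pairs)
  below <- which(!is.na(bins$mean_r2) & bins$mean_r2 < r2_threshold)
  decay <- if (length(below)) bins$bin_start[below[1]] else NA_real_
  structure(list(bins = bins, decay_distance_bp = decay,
                 threshold = r2_threshold, n_pairs_used = nrow(sig)),
            class = "ld_decay")
}

#' Minimum marker count for LD mapping
#'
#' Rule-of-thumb marker budget for a genome-wide association panel: one
#' marker per LD-decay interval, i.e. genome size divided by the decay
#' distance, rounded to the nearest integer.
#'
#' @param genome_size_kb genome size in kb.
#' @param decay_kb LD decay distance in kb.
#' @return Integer marker count.
#' @export
min_markers_for_gwas <- function(genome_size_kb, decay_kb) {
  if (genome_size_kb <= 0 || decay_kb <= 0)
    stop("genome size and decay distance must be positive")
  as.integer(round(genome_size_kb / decay_kb))
}
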