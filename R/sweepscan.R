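#' Regions of elevated PC loadings
#'
#' Clusters loci whose absolute loading on a principal component exceeds
#' `threshold` into regions by single-linkage along each chromosome: two
#' high-loading loci join the same region when separated by at most
#' `gap_bp`. Regions with fewer than `min_snps` member loci are
#' discarded. Loading signs are ignored (eigenvector sign is arbitrary).
#'
#' @param pca a `pca_result` from [run_pca()].
#' @param vt the [variant_table()] the PCA was computed on (same locus
#'   order).
#' @param component which PC to scan (default 1).
#' @param threshold absolute-loading cutoff.
#' @param gap_bp single-linkage join distance in bp.
#' @param min_snps minimum member loci per region.
#' @return data.frame: chrom, start, end, n_snps, max_loading.
#' @export
loading_regions <- function(pca, vt, component = 1L, threshold = 0.02,
                            gap_bp = 5e5, min_snps = 5L) {
  if (component < 1 || component > ncol(pca$loadings))
    stop("component index out of range")
  load <- abs(pca$loadings[, component])
  if (length(load) != nrow(vt))
    stop("loadings are not aligned to the variant table")
  hi <- which(!is.na(load) & load > threshold)
  out <- list()
  for (ch in unique(vt$chrom[hi])) {
    sel <- hi[vt$chrom[hi] == ch]
    sel <- sel[order(vt$pos[sel])]
    pos <- vt$pos[sel]
    brk <- c(0L, which(diff(pos) > gap_bp), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      members <- sel[(brk[b] + 1L):brk[b + 1L]]
      if (length(members) < min_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(vt$pos[members]),
        end = max(vt$pos[members]), n_snps = length(members),
        max_loading = max(load[members]))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      max_loading = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Windows with outlying F_ST
#'
#' Flags windows whose F_ST is at least `z` standard deviations above
#' the mean of all finite windowed values, and merges runs of adjacent
#' outlier windows into single intervals. A panel with (near-)constant
#' windowed F_ST has no meaningful threshold and returns no windows,
#' with a flag.
#'
#' @param wt windowed F_ST table (chrom, start, end, fst) from
#'   [weir_cockerham_fst()] with `mode = "windowed"`.
#' @param z outlier threshold in standard deviations.
#' @return data.frame: chrom, start, end, n_windows, max_fst; attribute
#'   `degenerate` TRUE when the windowed sd was zero.
#' @export
fst_outlier_windows <- function(wt, z = 3.0) {
  fst <- wt$fst[is.finite(wt$fst)]
  if (length(fst) < 10)
    stop("need at least 10 finite F_ST windows for a stable threshold")
  mu <- mean(fst); sdev <- stats::sd(fst)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_fst = numeric())
  if (sdev == 0) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  cut <- mu + z * sdev
  out_rows <- which(is.finite(wt$fst) & wt$fst >= cut)
  if (!length(out_rows)) {
    attr(empty, "degenerate") <- FALSE
    return(empty)
  }
  merged <- list()
  ord <- out_rows[order(wt$chrom[out_rows], wt$start[out_rows])]
  cur <- wt[ord[1], ]
  cur_n <- 1L; cur_max <- wt$fst[ord[1]]
  flush <- function(acc, cur, n, mx) {
    acc[[length(acc) + 1L]] <- data.frame(chrom = cur$chrom,
                                          start = cur$start, end = cur$end,
                                          n_windows = n, max_fst = mx)
    acc
  }
  if (length(ord) > 1) {
    for (r in ord[-1]) {
      w <- wt[r, ]
      if (w$chrom == cur$chrom && w$start == cur$end) {
        cur$end <- w$end; cur_n <- cur_n + 1L
        cur_max <- max(cur_max, w$fst)
      } else {
        merged <- flush(merged, cur, cur_n, cur_max)
        cur <- w; cur_n <- 1L; cur_max <- w$fst
      }
    }
  }
  merged <- flush(merged, cur, cur_n, cur_max)
  res <- do.call(rbind, merged)
  attr(res, "degenerate") <- FALSE
  res
}

#' Integrate evidence tracks into regions of interest
#'
#' Pools three interval evidence tracks — PC-loading regions, F_ST
#' outlier runs, and haplotype blocks at least `min_block_kb` long —
#' computes maximal connected overlap components on each chromosome, and
#' reports components supported by at least `min_evidence` distinct
#' evidence types as regions of interest (ROI) spanning the union of
#' their member intervals.
#'
#' @param loadings data.frame from [loading_regions()].
#' @param fst_runs data.frame from [fst_outlier_windows()].
#' @param blocks data.frame from [gabriel_blocks()].
#' @param min_block_kb minimum block size (kb) to count as evidence.
#' @param min_evidence minimum number of distinct evidence types.
#' @return data.frame of class `roi_table`: chrom, start, end, evidence
#'   (comma-separated subset of loading/fst/block), n_evidence.
#' @export
integrate_roi <- function(loadings, fst_runs, blocks, min_block_kb = 400,
                          min_evidence = 2L) {
  take <- function(df, type, cols = c("chrom", "start", "end")) {
    if (is.null(df) || !nrow(df)) return(NULL)
    out <- df[, cols]
    out$type <- type
    out
  }
  ev <- rbind(take(loadings, "loading"), take(fst_runs, "fst"),
              take(blocks[blocks$size_kb >= min_block_kb, , drop = FALSE],
                   "block"))
  empty <- structure(data.frame(chrom = character(), start = integer(),
                                end = integer(), evidence = character(),
                                n_evidence = integer()),
                     class = c("roi_table", "data.frame"))
  if (is.null(ev) || !nrow(ev)) return(empty)
  out <- list()
  for (ch in unique(ev$chrom)) {
    e <- ev[ev$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    comp_start <- e$start[1]; comp_end <- e$end[1]
    comp_types <- e$type[1]
    flush <- function() {
      types <- sort(unique(comp_types))
      if (length(types) >= min_evidence)
        out[[length(out) + 1L]] <<- data.frame(
          chrom = ch, start = comp_start, end = comp_end,
          evidence = paste(types, collapse = ","),
          n_evidence = length(types))
    }
    if (nrow(e) > 1) {
      for (r in 2:nrow(e)) {
        if (e$start[r] <= comp_end) {
          comp_end <- max(comp_end, e$end[r])
          comp_types <- c(comp_types, e$type[r])
        } else {
          flush()
          comp_start <- e$start[r]; comp_end <- e$end[r]
          comp_types <- e$type[r]
        }
      }
    }
    flush()
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("roi_table", "data.frame")
  res
}

#' Regional PCA of a region of interest
#'
#' Re-runs PCA restricted to the SNPs inside an ROI and summarises how
#' strongly the region separates the provided subpopulation labels: the
#' variance explained by the first two and first five PCs, and the mean
#' silhouette width of the labels on the first-two-PC scores.
#'
#' @param gm a complete (imputed) [geno_matrix()].
#' @param vt matching [variant_table()].
#' @param roi one ROI row (list or single-row data.frame with chrom,
#'   start, end).
#' @param labels subpopulation label per sample (2+ groups for the
#'   silhouette; `"admixed"` samples are ignored for the silhouette).
#' @return list: n_snps, var_pc2, var_pc5, silhouette (NA when
#'   undefined).
#' @export
regional_pca <- function(gm, vt, roi, labels) {
  stopifnot_samples_match(gm, labels)
  loci <- which(vt$chrom == roi$chrom & vt$pos >= roi$start &
                  vt$pos <= roi$end)
  na_out <- list(n_snps = length(loci), var_pc2 = NA_real_,
                 var_pc5 = NA_real_, silhouette = NA_real_)
  if (length(loci) < 2) return(na_out)
  sub <- gm[, loci]
  p <- colMeans(sub$dosage) / 2
  if (sum(p > 0 & p < 1, na.rm = TRUE) < 2) return(na_out)
  pca <- run_pca(sub)
  ve <- pca$variance_explained
  var_pc2 <- sum(ve[seq_len(min(2, length(ve)))])
  var_pc5 <- sum(ve[seq_len(min(5, length(ve)))])
  sil <- NA_real_
  core <- labels != "admixed"
  if (length(unique(labels[core])) >= 2) {
    sc <- pca$scores[core, seq_len(min(2, ncol(pca$scores))), drop = FALSE]
    cl <- as.integer(factor(labels[core]))
    sw <- cluster::silhouette(cl, stats::dist(sc))
    sil <- mean(sw[, "sil_width"])
  }
  list(n_snps = length(loci), var_pc2 = var_pc2, var_pc5 = var_pc5,
       silhouette = sil)
}

#' Full sweep scan on a panel
#'
#' Convenience wrapper chaining [run_pca()] + [loading_regions()],
#' windowed [weir_cockerham_fst()] + [fst_outlier_windows()], and
#' [ld_dprime()] + [gabriel_blocks()] into [integrate_roi()], then
#' annotating each ROI with its [regional_pca()] summary.
#'
#' @param gm complete (imputed) [geno_matrix()].
#' @param vt matching [variant_table()].
#' @param labels subpopulation label per sample.
#' @param window F_ST window size in bp.
#' @param ld_window_bp pair window for the D' table.
#' @param loading_threshold,gap_bp,min_snps passed to
#'   [loading_regions()].
#' @param fst_z passed to [fst_outlier_windows()].
#' @param min_block_kb,min_evidence passed to [integrate_roi()].
#' @return list: `roi` (ROI table with regional-PCA columns),
#'   `loadings`, `fst_runs`, `blocks`, `fst_windows`.
#' @export
sweep_scan <- function(gm, vt, labels, window = 1e5, ld_window_bp = 5e5,
                       loading_threshold = 0.02, gap_bp = 5e5,
                       min_snps = 5L, fst_z = 3.0, min_block_kb = 400,
                       min_evidence = 2L) {
  pca <- run_pca(gm)
  lr <- loading_regions(pca, vt, threshold = loading_threshold,
                        gap_bp = gap_bp, min_snps = min_snps)
  wfst <- weir_cockerham_fst(gm, labels, mode = "windowed", vt = vt,
                             window = window)
  runs <- fst_outlier_windows(wfst, z = fst_z)
  dp <- ld_dprime(gm, vt, window_bp = ld_window_bp)
  blocks <- gabriel_blocks(dp, vt)
  roi <- integrate_roi(lr, runs, blocks, min_block_kb = min_block_kb,
                       min_evidence = min_evidence)
  if (nrow(roi)) {
    extra <- lapply(seq_len(nrow(roi)), function(r)
      regional_pca(gm, vt, roi[r, ], labels))
    roi$n_snps <- vapply(extra, `[[`, 0, "n_snps")
    roi$var_pc2 <- vapply(extra, `[[`, 0, "var_pc2")
    roi$var_pc5 <- vapply(extra, `[[`, 0, "var_pc5")
    roi$silhouette <- vapply(extra, `[[`, 0, "silhouette")
    roi$max_fst <- vapply(seq_len(nrow(roi)), function(r) {
      ov <- wfst$chrom == roi$chrom[r] & wfst$start < roi$end[r] &
        wfst$end > roi$start[r] & is.finite(wfst$fst)
      if (any(ov)) max(wfst$fst[ov]) else NA_real_
    }, 0)
    # rank: most independent evidence first, strongest F_ST peak breaks ties
    ord <- order(-roi$n_evidence,
                 -ifelse(is.na(roi$max_fst), -Inf, roi$max_fst))
    roi$rank <- integer(nrow(roi))
    roi$rank[ord] <- seq_len(nrow(roi))
  }
  list(roi = roi, loadings = lr, fst_runs = runs, blocks = blocks,
       fst_windows = wfst)
}
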