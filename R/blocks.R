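# Vectorised two-locus haplotype-frequency EM and D' likelihood CIs.
# All inputs are parallel vectors over locus pairs: c_xy holds the count
# of samples with dosage x at the first locus and y at the second.
dprime_ci_core <- function(counts, max_iter = 1000L, tol = 1e-10) {
  cN <- rowSums(counts)
  c00 <- counts[, "c00"]; c01 <- counts[, "c01"]; c02 <- counts[, "c02"]
  c10 <- counts[, "c10"]; c11 <- counts[, "c11"]; c12 <- counts[, "c12"]
  c20 <- counts[, "c20"]; c21 <- counts[, "c21"]; c22 <- counts[, "c22"]
  # fixed known haplotype contributions
  k00 <- 2 * c00 + c01 + c10
  k01 <- 2 * c02 + c01 + c12
  k10 <- 2 * c20 + c10 + c21
  k11 <- 2 * c22 + c12 + c21
  tot <- 2 * cN
  f00 <- (k00 + 0.5 * c11) / tot
  f01 <- (k01 + 0.5 * c11) / tot
  f10 <- (k10 + 0.5 * c11) / tot
  f11 <- (k11 + 0.5 * c11) / tot
  converged <- rep(FALSE, length(cN))
  active <- seq_along(cN)   # only unconverged pairs are iterated
  for (it in seq_len(max_iter)) {
    a <- active
    denom <- f00[a] * f11[a] + f01[a] * f10[a]
    pc <- ifelse(denom > 0, f00[a] * f11[a] / denom, 0.5)
    n00 <- (k00[a] + pc * c11[a]) / tot[a]
    n01 <- (k01[a] + (1 - pc) * c11[a]) / tot[a]
    n10 <- (k10[a] + (1 - pc) * c11[a]) / tot[a]
    n11 <- (k11[a] + pc * c11[a]) / tot[a]
    delta <- pmax(abs(n00 - f00[a]), abs(n01 - f01[a]),
                  abs(n10 - f10[a]), abs(n11 - f11[a]))
    f00[a] <- n00; f01[a] <- n01; f10[a] <- n10; f11[a] <- n11
    done <- delta < tol
    converged[a[done]] <- TRUE
    active <- a[!done]
    if (!length(active)) break
  }
  pA <- f10 + f11   # ALT frequency, locus 1
  pB <- f01 + f11   # ALT frequency, locus 2
  D <- f11 - pA * pB
  dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dprime <- ifelse(dmax > 0, abs(D) / dmax, 0)
  # likelihood profile of |D'| on a 0..1 grid, allele margins fixed,
  # normalised to a posterior with flat prior; 5th/95th percentiles
  grid <- seq(0, 1, by = 0.01)
  sgn <- ifelse(D >= 0, 1, -1)
  eps <- 1e-12
  np <- length(cN)
  ll <- matrix(NA_real_, np, length(grid))
  for (gi in seq_along(grid)) {
    Dg <- sgn * grid[gi] * dmax
    h11 <- pA * pB + Dg
    h10 <- pA - h11
    h01 <- pB - h11
    h00 <- 1 - pA - pB + h11
    h11 <- pmax(h11, eps); h10 <- pmax(h10, eps)
    h01 <- pmax(h01, eps); h00 <- pmax(h00, eps)
    ll[, gi] <- c00 * log(h00^2) + c01 * log(2 * h00 * h01) +
      c02 * log(h01^2) + c10 * log(2 * h00 * h10) +
      c11 * log(2 * (h00 * h11 + h01 * h10)) +
      c12 * log(2 * h01 * h11) + c20 * log(h10^2) +
      c21 * log(2 * h10 * h11) + c22 * log(h11^2)
  }
  # normalise per pair and read the 5th/95th posterior percentiles off
  # the cumulative, column by column (cheaper than per-row apply)
  mx <- ll[, 1]
  for (gi in 2:ncol(ll)) mx <- pmax(mx, ll[, gi])
  tot <- numeric(np)
  for (gi in seq_len(ncol(ll))) {
    ll[, gi] <- exp(ll[, gi] - mx)
    tot <- tot + ll[, gi]
  }
  acc <- numeric(np)
  n_low <- integer(np); n_high <- integer(np)
  for (gi in seq_len(ncol(ll))) {
    acc <- acc + ll[, gi]
    n_low <- n_low + (acc < 0.05 * tot)
    n_high <- n_high + (acc < 0.95 * tot)
  }
  data.frame(dprime = dprime, ci_low = grid[n_low + 1L],
             ci_high = grid[n_high + 1L], converged = converged)
}

pair_genotype_counts <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  tab <- table(factor(x[ok], levels = 0:2), factor(y[ok], levels = 0:2))
  m <- matrix(as.integer(tab), 1, 9)
  colnames(m) <- c("c00", "c10", "c20", "c01", "c11", "c21", "c02", "c12",
                   "c22")
  m[, c("c00", "c01", "c02", "c10", "c11", "c12", "c20", "c21", "c22"),
    drop = FALSE]
}

#' D' and its confidence interval for one locus pair
#'
#' Estimates the two-locus haplotype frequencies from unphased genotypes
#' by EM, reports \eqn{|D'|}, and derives a confidence interval by
#' profiling the data likelihood over \eqn{|D'| \in \{0, 0.01, ..., 1\}}
#' (allele margins fixed at their estimates), normalising to a posterior
#' with a flat prior, and taking its 5th and 95th percentiles — the
#' quantities that drive the Gabriel haplotype-block classification.
#'
#' @param x,y dosage vectors (0/1/2/NA) of the two loci.
#' @return list(dprime, ci_low, ci_high, converged).
#' @export
dprime_ci <- function(x, y) {
  counts <- pair_genotype_counts(x, y)
  pA <- (counts %*% c(0, 0, 0, 1, 1, 1, 2, 2, 2))[1] / (2 * sum(counts))
  pB <- (counts %*% c(0, 1, 2, 0, 1, 2, 0, 1, 2))[1] / (2 * sum(counts))
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("both loci must be polymorphic in the complete subset")
  as.list(dprime_ci_core(counts))
}

#' D'-confidence-interval table for all close pairs
#'
#' Runs the haplotype EM and D' CI computation of [dprime_ci()] for
#' every same-chromosome locus pair within `window_bp`, vectorised
#' across pairs.
#'
#' @param gm a [geno_matrix()].
#' @param vt matching [variant_table()].
#' @param window_bp maximum pair separation in bp.
#' @return data.frame: i, j, chrom, pos_i, pos_j, dist_bp, dprime,
#'   ci_low, ci_high, converged. Monomorphic pairs are omitted.
#' @export
ld_dprime <- function(gm, vt, window_bp = 5e5) {
  d <- gm$dosage
  acc_i <- list(); acc_j <- list()
  for (ch in unique(vt$chrom)) {
    sel <- which(vt$chrom == ch)
    pos <- vt$pos[sel]
    for (a in seq_along(sel)) {
      b <- which(pos > pos[a] & pos <= pos[a] + window_bp)
      b <- b[b > a]
      if (length(b)) {
        acc_i[[length(acc_i) + 1L]] <- rep(sel[a], length(b))
        acc_j[[length(acc_j) + 1L]] <- sel[b]
      }
    }
  }
  pair_i <- unlist(acc_i) %||% integer(0)
  pair_j <- unlist(acc_j) %||% integer(0)
  if (!length(pair_i))
    return(data.frame(i = integer(), j = integer(), chrom = character(),
                      pos_i = integer(), pos_j = integer(),
                      dist_bp = integer(), dprime = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      converged = logical()))
  # 3x3 genotype-pair counts, vectorised over pairs: encode each call
  # pair as a single code 0..8 (NA propagates) and count per column
  X <- d[, pair_i, drop = FALSE]; Y <- d[, pair_j, drop = FALSE]
  code <- X * 3L + Y
  counts <- matrix(0L, length(pair_i), 9,
                   dimnames = list(NULL, c("c00", "c01", "c02", "c10",
                                           "c11", "c12", "c20", "c21",
                                           "c22")))
  for (k in 0:8)
    counts[, k + 1L] <- colSums(code == k, na.rm = TRUE)
  pA <- colMeans(X, na.rm = TRUE) / 2
  pB <- colMeans(Y, na.rm = TRUE) / 2
  poly <- pA > 0 & pA < 1 & pB > 0 & pB < 1 & rowSums(counts) > 0
  if (!any(poly))
    return(data.frame(i = integer(), j = integer(), chrom = character(),
                      pos_i = integer(), pos_j = integer(),
                      dist_bp = integer(), dprime = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      converged = logical()))
  res <- dprime_ci_core(counts[poly, , drop = FALSE])
  out <- data.frame(i = pair_i[poly], j = pair_j[poly],
                    chrom = vt$chrom[pair_i[poly]],
                    pos_i = vt$pos[pair_i[poly]],
                    pos_j = vt$pos[pair_j[poly]],
                    dist_bp = vt$pos[pair_j[poly]] - vt$pos[pair_i[poly]],
                    dprime = res$dprime, ci_low = res$ci_low,
                    ci_high = res$ci_high, converged = res$converged)
  rownames(out) <- NULL
  out
}

#' Gabriel-style haplotype blocks
#'
#' Classifies each CI-annotated pair as strong LD (`ci_low >= 0.70` and
#' `ci_high >= 0.98`), strong recombination (`ci_high < 0.90`), or
#' non-informative. A candidate block spans loci i..j when the endpoint
#' pair (i, j) is in strong LD and at least `min_strong_frac` of the
#' informative pairs inside the interval are in strong LD. Overlapping
#' candidates are resolved largest-bp-span first (ties: leftmost), and
#' overlapped candidates discarded. This is the plain Gabriel rule;
#' block-size-dependent refinements of desktop tools are deliberately
#' not applied.
#'
#' @param pairs output of [ld_dprime()]; non-converged pairs are
#'   excluded.
#' @param vt matching [variant_table()].
#' @param strong_ci_low,strong_ci_high strong-LD bounds on the D' CI.
#' @param recomb_ci_high strong-recombination bound.
#' @param min_strong_frac minimum fraction of informative pairs inside a
#'   block that must show strong LD.
#' @return data.frame: chrom, first, last (locus indices), start, end
#'   (bp), n_snps, size_kb.
#' @export
gabriel_blocks <- function(pairs, vt, strong_ci_low = 0.70,
                           strong_ci_high = 0.98, recomb_ci_high = 0.90,
                           min_strong_frac = 0.95) {
  empty <- data.frame(chrom = character(), first = integer(),
                      last = integer(), start = integer(), end = integer(),
                      n_snps = integer(), size_kb = numeric())
  if (!nrow(pairs)) return(empty)
  pairs <- pairs[pairs$converged, , drop = FALSE]
  strong <- pairs$ci_low >= strong_ci_low & pairs$ci_high >= strong_ci_high
  recomb <- pairs$ci_high < recomb_ci_high
  informative <- strong | recomb
  cand <- list()
  for (ch in unique(pairs$chrom)) {
    sel <- which(vt$chrom == ch)
    idx <- stats::setNames(seq_along(sel), sel)  # global -> local
    pc <- pairs$chrom == ch
    li <- idx[as.character(pairs$i[pc])]
    lj <- idx[as.character(pairs$j[pc])]
    m <- length(sel)
    Sm <- matrix(0L, m, m); Im <- matrix(0L, m, m)
    Sm[cbind(li, lj)] <- as.integer(strong[pc])
    Im[cbind(li, lj)] <- as.integer(informative[pc])
    # prefix sums over rows/cols: pairs inside [i..j] = P[j,j] - P[i-1,j]
    PS <- t(apply(apply(Sm, 2, cumsum), 1, cumsum))
    PI <- t(apply(apply(Im, 2, cumsum), 1, cumsum))
    ends <- which(Sm == 1L, arr.ind = TRUE)
    if (!nrow(ends)) next
    for (e in seq_len(nrow(ends))) {
      i <- ends[e, 1]; j <- ends[e, 2]
      if (j - i < 1) next
      n_inf <- PI[j, j] - if (i > 1) PI[i - 1, j] else 0
      n_str <- PS[j, j] - if (i > 1) PS[i - 1, j] else 0
      if (n_inf > 0 && n_str / n_inf >= min_strong_frac) {
        gi <- sel[i]; gj <- sel[j]
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = ch, first = gi, last = gj,
          start = vt$pos[gi], end = vt$pos[gj],
          n_snps = j - i + 1L,
          size_kb = (vt$pos[gj] - vt$pos[gi]) / 1000)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  taken <- list()
  for (r in seq_len(nrow(cand))) {
    ch <- cand$chrom[r]
    ov <- FALSE
    for (t in taken) {
      if (t$chrom == ch && cand$first[r] <= t$last && cand$last[r] >= t$first) {
        ov <- TRUE; break
      }
    }
    if (!ov) taken[[length(taken) + 1L]] <- cand[r, ]
  }
  res <- do.call(rbind, taken)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
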