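#' Greedy LD pruning
#'
#' Left-to-right scan along each chromosome: a locus is dropped when its
#' composite (dosage-correlation) \eqn{r^2} with any retained locus
#' within `window_bp` upstream exceeds `r2_max`. At equal positions the
#' locus with higher MAF is considered first (and hence kept). The
#' retained subset contains no within-window pair with \eqn{r^2 >}
#' `r2_max`.
#'
#' @param gm a [geno_matrix()].
#' @param vt matching [variant_table()] (sorted by position).
#' @param r2_max prune threshold (the conventional "unlinked" cutoff is
#'   0.1).
#' @param window_bp pairwise comparison window in bp.
#' @return Integer vector of retained locus indices (into `vt`).
#' @export
ld_prune <- function(gm, vt, r2_max = 0.1, window_bp = 5e5) {
  d <- gm$dosage
  maf <- locus_summary(d)$maf
  keep <- logical(nrow(vt))
  for (ch in unique(vt$chrom)) {
    sel <- which(vt$chrom == ch)
    ord <- sel[order(vt$pos[sel], -maf[sel])]
    kept <- integer(0)
    kept_pos <- integer(0)
    for (j in ord) {
      near <- kept[kept_pos >= vt$pos[j] - window_bp]
      ok <- TRUE
      if (length(near)) {
        r <- suppressWarnings(
          stats::cor(d[, j], d[, near, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r2 <- r^2
        if (any(r2 > r2_max, na.rm = TRUE)) ok <- FALSE
      }
      if (ok) {
        kept <- c(kept, j)
        kept_pos <- c(kept_pos, vt$pos[j])
      }
    }
    keep[kept] <- TRUE
  }
  which(keep)
}

#' Principal component analysis of a genotype matrix
#'
#' Centers each locus at twice its ALT frequency and (optionally,
#' Patterson-style) scales by \eqn{\sqrt{\hat p (1 - \hat p)}}, then
#' eigendecomposes the sample configuration. Monomorphic loci are
#' dropped. Component signs are fixed so the largest-magnitude loading
#' of each component is positive, making runs reproducible.
#'
#' @param gm a [geno_matrix()] with no missing calls.
#' @param scaling `"patterson"` or `"center_only"`.
#' @return A list of class `pca_result`: `scores` (samples x
#'   components), `loadings` (loci x components, unit-norm columns, NA
#'   rows for dropped monomorphic loci), `variance_explained`,
#'   `kept_loci` (indices of polymorphic loci).
#' @export
run_pca <- function(gm, scaling = c("patterson", "center_only")) {
  scaling <- match.arg(scaling)
  d <- gm$dosage
  if (any(is.na(d))) stop("PCA requires a complete matrix; impute first")
  if (nrow(d) < 2 || ncol(d) < 2) stop("need at least 2 samples and 2 loci")
  p <- colMeans(d) / 2
  v <- colMeans(d^2) - colMeans(d)^2
  poly <- p > 0 & p < 1 & v > 0
  if (!any(poly)) stop("matrix is constant: no variable loci")
  x <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  if (scaling == "patterson")
    x <- sweep(x, 2, sqrt(p[poly] * (1 - p[poly])), "/")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  rot <- sweep(pc$rotation, 2, flip, "*")
  loadings <- matrix(NA_real_, ncol(d), ncol(rot))
  loadings[poly, ] <- rot
  rownames(loadings) <- colnames(d)
  colnames(loadings) <- colnames(rot)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = pc$sdev^2 / sum(pc$sdev^2),
                 kept_loci = which(poly)),
            class = "pca_result")
}

#' Maximum-likelihood admixture via EM
#'
#' Fits the classic admixture model — genotype \eqn{g_{il} \sim
#' \mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})} — by alternating EM
#' updates of the membership matrix Q (rows on the simplex) and the
#' ancestral allele frequencies P (clamped to `[1e-6, 1-1e-6]`). This is
#' the same likelihood that Bayesian model-based clustering programs
#' sample from; the maximum-likelihood fit is deterministic given the
#' seed and runs at desk scale. The log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' @param gm a [geno_matrix()] with no missing calls.
#' @param K number of ancestral clusters (1..n samples).
#' @param seed integer seed for the random Dirichlet initialisation.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood gain drops below this.
#' @return A list of class `admixture_result`: `K`, `Q`, `P`, `loglik`,
#'   `n_iter`, `seed`, `converged`.
#' @export
admixture_em <- function(gm, K, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  g <- gm$dosage
  if (any(is.na(g))) stop("admixture_em requires a complete matrix")
  n <- nrow(g); L <- ncol(g)
  if (K < 1 || K > n) stop("K must lie between 1 and the number of samples")
  set.seed(seed)
  eps <- 1e-6
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  p_hat <- colMeans(g) / 2
  P <- pmin(pmax(matrix(rep(p_hat, each = K), K, L) +
                   matrix(stats::runif(K * L, -0.1, 0.1), K, L), eps), 1 - eps)
  const <- sum(lchoose(2, g))
  loglik_of <- function(PI) const + sum(g * log(PI) + (2 - g) * log(1 - PI))
  PI <- Q %*% P
  ll <- loglik_of(PI)
  n_iter <- 0L; converged <- FALSE
  g2 <- 2 - g
  for (it in seq_len(max_iter)) {
    A <- g / PI        # n x L
    B <- g2 / (1 - PI)
    # expected allele counts attributed to each cluster
    Qnum <- Q * (A %*% t(P)) + Q * (B %*% t(1 - P))
    Qn <- Qnum / (2 * L)
    Pnum <- P * (t(Q) %*% A)
    Pden <- Pnum + (1 - P) * (t(Q) %*% B)
    Pn <- pmin(pmax(Pnum / Pden, eps), 1 - eps)
    Qn <- Qn / rowSums(Qn)
    PI_new <- Qn %*% Pn
    ll_new <- loglik_of(PI_new)
    if (ll_new < ll - 1e-6)
      stop("EM log-likelihood decreased (", ll, " -> ", ll_new, ")")
    Q <- Qn; P <- Pn; PI <- PI_new
    n_iter <- it
    if (ll_new - ll < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  colnames(Q) <- paste0("Q", seq_len(K))
  structure(list(K = K, Q = Q, P = P, loglik = ll, n_iter = n_iter,
                 seed = seed, converged = converged),
            class = "admixture_result")
}

# Evanno second-difference statistic: |L(K+1) - 2 L(K) + L(K-1)| / sd(K),
# defined only for interior K; sd = 0 gives the Inf sentinel.
evanno_delta_k <- function(mean_ll, sd_ll) {
  nk <- length(mean_ll)
  dk <- rep(NA_real_, nk)
  for (ki in seq_len(nk)) {
    if (ki == 1 || ki == nk) next
    curv <- abs(mean_ll[ki + 1] - 2 * mean_ll[ki] + mean_ll[ki - 1])
    dk[ki] <- if (sd_ll[ki] > 0) curv / sd_ll[ki] else Inf
  }
  dk
}

#' Evanno delta-K model selection
#'
#' Runs [admixture_em()] for each K in `k_range` with `replicates`
#' seeded restarts, and computes the ad hoc second-difference statistic
#' \deqn{\Delta K = |\bar L(K+1) - 2 \bar L(K) + \bar L(K-1)| / sd(L(K))}
#' over replicate log-likelihoods. The chosen K maximises delta-K over
#' the interior of the range. A zero replicate standard deviation yields
#' an infinite sentinel and is flagged; an all-zero curvature (linear
#' log-likelihood in K) flags the selection as ambiguous.
#'
#' @param gm a [geno_matrix()] with no missing calls.
#' @param k_range integer vector of K values (at least 3, contiguous).
#' @param replicates restarts per K (>= 2, for the standard deviation).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param ... passed to [admixture_em()].
#' @return A list of class `k_selection`: `table` (K, mean_loglik,
#'   sd_loglik, delta_k), `logliks` (replicates x K), `chosen_k`,
#'   `ambiguous`, `best_fit` (the highest-likelihood run at `chosen_k`).
#' @export
select_k <- function(gm, k_range = 1:10, replicates = 5L, seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) stop("k_range must contain at least 3 K values")
  if (replicates < 2) stop("need >= 2 replicates to compute sd")
  fits <- list()
  ll <- matrix(NA_real_, replicates, length(k_range),
               dimnames = list(NULL, paste0("K", k_range)))
  for (ki in seq_along(k_range)) {
    for (r in seq_len(replicates)) {
      fit <- admixture_em(gm, k_range[ki],
                          seed = derive_seed(seed, ki * 1000 + r), ...)
      ll[r, ki] <- fit$loglik
      if (length(fits) < ki || is.null(fits[[ki]]) ||
          fit$loglik > fits[[ki]]$loglik)
        fits[[ki]] <- fit
    }
  }
  mean_ll <- colMeans(ll); sd_ll <- apply(ll, 2, stats::sd)
  dk <- evanno_delta_k(mean_ll, sd_ll)
  interior <- which(!is.na(dk))
  ambiguous <- all(dk[interior] == 0) || any(is.infinite(dk[interior]))
  chosen <- k_range[interior[which.max(dk[interior])]]
  structure(list(table = data.frame(K = k_range, mean_loglik = mean_ll,
                                    sd_loglik = sd_ll, delta_k = dk),
                 logliks = ll, chosen_k = chosen, ambiguous = ambiguous,
                 best_fit = fits[[match(chosen, k_range)]]),
            class = "k_selection")
}

#' Assign samples to subpopulations from a Q matrix
#'
#' A sample is assigned to its majority cluster when the membership
#' coefficient reaches `threshold` (inclusive); otherwise it is labelled
#' `"admixed"`.
#'
#' @param Q samples x K membership matrix (rows sum to 1).
#' @param threshold assignment cutoff (default 0.70).
#' @return Character vector of cluster labels (`"SP1"`.. or `"admixed"`).
#' @export
assign_membership <- function(Q, threshold = 0.70) {
  Q <- as.matrix(Q)
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("Q rows must sum to 1")
  best <- max.col(Q, ties.method = "first")
  lab <- paste0("SP", best)
  lab[Q[cbind(seq_len(nrow(Q)), best)] < threshold] <- "admixed"
  lab
}
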