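#' Per-locus allele statistics
#'
#' Computes, from observed calls only, the ALT frequency, minor allele
#' frequency, expected heterozygosity (gene diversity,
#' \eqn{H_E = 1 - p^2 - q^2}), observed heterozygote fraction
#' \eqn{H_O}, and polymorphism information content
#' (\eqn{PIC = H_E - 2 p^2 q^2} for a biallelic locus).
#'
#' @param gm a [geno_matrix()].
#' @param vt optional [variant_table()] whose chrom/pos/name columns are
#'   carried through.
#' @return data.frame with one row per locus: snp_name, chrom, pos,
#'   n_obs, p_alt, maf, he, ho, pic. Loci with no observed calls get NA.
#' @export
allele_stats <- function(gm, vt = NULL) {
  ls <- locus_summary(gm$dosage)
  p <- ls$p_alt; q <- 1 - p
  he <- 1 - p^2 - q^2
  pic <- he - 2 * p^2 * q^2
  out <- data.frame(
    snp_name = colnames(gm$dosage) %||% paste0("locus", seq_along(p)),
    chrom = if (!is.null(vt)) vt$chrom else NA_character_,
    pos = if (!is.null(vt)) vt$pos else NA_integer_,
    n_obs = ls$n_obs, p_alt = p, maf = ls$maf,
    he = he, ho = ls$het_rate, pic = pic,
    stringsAsFactors = FALSE)
  out$he[ls$n_obs == 0] <- NA_real_
  out$pic[ls$n_obs == 0] <- NA_real_
  out
}

#' Summarise diversity for a set of loci
#'
#' Mean \eqn{H_E}, \eqn{H_O} and PIC over (a subset of) loci, as used for
#' whole-genome / subgenome / subpopulation diversity tables.
#'
#' @param gm a [geno_matrix()].
#' @param vt matching [variant_table()].
#' @param loci optional locus index or logical mask.
#' @param scope label for the summary row.
#' @return One-row data.frame: scope, n_snps, n_polymorphic, he, ho, pic.
#' @export
diversity_summary <- function(gm, vt, loci = NULL, scope = "all") {
  if (is.null(loci)) loci <- seq_len(ncol(gm$dosage))
  st <- allele_stats(gm[, loci], vt[loci, , drop = FALSE])
  data.frame(scope = scope, n_snps = nrow(st),
             n_polymorphic = sum(st$maf > 0, na.rm = TRUE),
             he = mean(st$he, na.rm = TRUE),
             ho = mean(st$ho, na.rm = TRUE),
             pic = mean(st$pic, na.rm = TRUE), stringsAsFactors = FALSE)
}

# Tajima's D normalisation constants for sample size n (haploid sequences).
tajima_constants <- function(n) {
  if (n < 2) return(NULL)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Tile a chromosome extent with half-open windows [start, start+size).
make_windows <- function(chrom_max, size) {
  starts <- seq(0L, by = as.integer(size),
                length.out = ceiling(chrom_max / size))
  data.frame(start = starts, end = starts + as.integer(size))
}

#' Windowed nucleotide diversity statistics
#'
#' Per non-overlapping window: the number of SNPs and segregating sites,
#' per-site nucleotide diversity \eqn{\pi}, Watterson's \eqn{\theta_W},
#' Tajima's D, and mean observed heterozygosity. Sites are treated as
#' pseudo-haplotype samples of size \eqn{n_l = 2 \times} (non-missing
#' samples): the mean pairwise difference at a site is the unbiased
#' \eqn{\frac{n_l}{n_l - 1} 2 \hat p \hat q}, summed over sites and
#' divided by the full window length (per-site reporting over the whole
#' window, matching sparse-GBS conventions). Watterson's estimator uses
#' the median per-site allele count of the window for its harmonic
#' constant, and the same n parameterises the Tajima normalisation.
#' Windows with \eqn{S \le 1} get `tajima_d = NA`; empty windows are all
#' NA.
#'
#' @param gm a [geno_matrix()].
#' @param vt matching [variant_table()].
#' @param window window size in bp (default 100 kb, non-overlapping).
#' @param loci optional locus subset (index or logical) to restrict the
#'   computation to, e.g. one annotation class; windows still tile the
#'   full chromosome.
#' @return data.frame: chrom, start, end (half-open), n_snps, S, pi,
#'   theta_w, tajima_d, mean_het.
#' @export
windowed_diversity <- function(gm, vt, window = 1e5, loci = NULL) {
  if (window <= 0) stop("window size must be positive")
  d <- gm$dosage
  if (!is.null(loci)) {
    keep <- if (is.logical(loci)) loci else seq_len(ncol(d)) %in% loci
    d <- d[, keep, drop = FALSE]
    vt <- vt[keep, , drop = FALSE]
  }
  out <- list()
  for (ch in unique(vt$chrom)) {
    sel <- which(vt$chrom == ch)
    pos <- vt$pos[sel]
    win <- make_windows(max(pos), window)
    wi <- findInterval(pos - 1L, win$start)  # half-open windows
    n_obs <- colSums(!is.na(d[, sel, drop = FALSE]))
    p <- colMeans(d[, sel, drop = FALSE], na.rm = TRUE) / 2
    het <- colMeans(d[, sel, drop = FALSE] == 1L, na.rm = TRUE)
    nl <- 2 * n_obs
    site_k <- ifelse(nl > 1, nl / (nl - 1) * 2 * p * (1 - p), 0)
    seg <- !is.na(p) & p > 0 & p < 1
    rows <- lapply(seq_len(nrow(win)), function(w) {
      in_w <- which(wi == w & nl > 0)
      n_snps <- length(in_w)
      if (n_snps == 0L)
        return(data.frame(chrom = ch, start = win$start[w], end = win$end[w],
                          n_snps = 0L, S = NA_integer_, pi = NA_real_,
                          theta_w = NA_real_, tajima_d = NA_real_,
                          mean_het = NA_real_))
      k_hat <- sum(site_k[in_w])
      S <- sum(seg[in_w])
      n_med <- stats::median(nl[in_w])
      tc <- tajima_constants(n_med)
      theta_w <- if (!is.null(tc)) S / (tc$a1 * window) else NA_real_
      D <- NA_real_
      if (!is.null(tc) && S > 1) {
        num <- k_hat - S / tc$a1
        den <- sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
        D <- if (den > 0) num / den else if (abs(num) < 1e-9) 0 else NA_real_
      }
      data.frame(chrom = ch, start = win$start[w], end = win$end[w],
                 n_snps = n_snps, S = S, pi = k_hat / window,
                 theta_w = theta_w, tajima_d = D,
                 mean_het = mean(het[in_w], na.rm = TRUE))
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Weir-Cockerham (1984) per-locus variance components from dosage data.
# Returns matrices of a (among populations), b (among individuals within
# populations) and c (within individuals) per locus.
wc_components <- function(dosage, labels) {
  pops <- sort(unique(labels))
  r <- length(pops)
  L <- ncol(dosage)
  n_i <- matrix(0, r, L); p_i <- matrix(0, r, L); h_i <- matrix(0, r, L)
  for (k in seq_len(r)) {
    dk <- dosage[labels == pops[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(dk))
    p_i[k, ] <- colMeans(dk, na.rm = TRUE) / 2
    h_i[k, ] <- colMeans(dk == 1L, na.rm = TRUE)
  }
  usable <- colSums(n_i > 0) == r
  n_bar <- colMeans(n_i)
  n_c <- (r * n_bar - colSums(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n_i * p_i) / (r * n_bar)
  s2 <- colSums(n_i * (p_i - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  bad <- !usable | n_bar <= 1 | !is.finite(a + b + cc)
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F-statistics
#'
#' Estimates \eqn{F_{ST}} (and for the multilocus mode also \eqn{F_{IS}}
#' and \eqn{F_{IT}}) with the Weir & Cockerham (1984) variance-component
#' estimator on observed genotype (dosage) data. Combined estimates are
#' ratio-of-sums \eqn{\sum a / \sum (a + b + c)} over the contributing
#' loci; loci with a non-positive total variance are excluded from the
#' combined ratios.
#'
#' @param gm a [geno_matrix()].
#' @param labels population label per sample (2 or more populations).
#' @param mode one of `"multilocus"` (single genome-wide estimate),
#'   `"per_locus"`, `"windowed"` (requires `vt`), or `"pairwise_pops"`
#'   (multilocus estimate for every population pair).
#' @param vt [variant_table()], required for `mode = "windowed"`.
#' @param window window size in bp for `mode = "windowed"`.
#' @return Depending on mode: a list with `fst`, `fis`, `fit`
#'   (multilocus); a numeric vector (per_locus); a data.frame of windows
#'   (windowed); or a data.frame of population pairs (pairwise_pops).
#' @export
weir_cockerham_fst <- function(gm, labels,
                               mode = c("multilocus", "per_locus",
                                        "windowed", "pairwise_pops"),
                               vt = NULL, window = 1e5) {
  mode <- match.arg(mode)
  stopifnot_samples_match(gm, labels)
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("need at least two populations")
  if (mode == "pairwise_pops") {
    prs <- utils::combn(pops, 2)
    res <- apply(prs, 2, function(pr) {
      sel <- labels %in% pr
      weir_cockerham_fst(gm[sel, ], labels[sel], mode = "multilocus")$fst
    })
    return(data.frame(pop1 = prs[1, ], pop2 = prs[2, ], fst = res,
                      stringsAsFactors = FALSE))
  }
  comp <- wc_components(gm$dosage, labels)
  tot <- comp$a + comp$b + comp$c
  if (mode == "per_locus") {
    fst <- comp$a / tot
    fst[!is.finite(fst)] <- NA_real_
    return(fst)
  }
  if (mode == "windowed") {
    if (is.null(vt)) stop("mode = 'windowed' requires a variant table")
    out <- list()
    for (ch in unique(vt$chrom)) {
      sel <- which(vt$chrom == ch)
      win <- make_windows(max(vt$pos[sel]), window)
      wi <- findInterval(vt$pos[sel] - 1L, win$start)
      fst_w <- vapply(seq_len(nrow(win)), function(w) {
        ii <- sel[wi == w]
        ok <- ii[which(is.finite(tot[ii]) & tot[ii] > 0)]
        if (!length(ok)) return(NA_real_)
        sum(comp$a[ok]) / sum(tot[ok])
      }, 0)
      out[[ch]] <- data.frame(chrom = ch, start = win$start,
                              end = win$end, fst = fst_w,
                              n_snps = tabulate(wi, nbins = nrow(win)))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }
  ok <- is.finite(tot) & tot > 0
  list(fst = sum(comp$a[ok]) / sum(tot[ok]),
       fis = 1 - sum(comp$c[ok]) / sum(comp$b[ok] + comp$c[ok]),
       fit = 1 - sum(comp$c[ok]) / sum(tot[ok]),
       n_loci = sum(ok))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical partition of genotypic variance into among-population,
#' among-individual-within-population, and within-individual components,
#' computed per locus on the two allele "draws" implied by the dosage
#' (0 = two REF alleles, 1 = one of each, 2 = two ALT) and summed over
#' loci with missing calls excluded per locus. Variance components come
#' from the standard nested expected-mean-square equations; negative
#' components are truncated to zero before percentages (the convention of
#' desktop AMOVA tools). Phi-statistics are reported from the truncated
#' components.
#'
#' @param gm a [geno_matrix()].
#' @param labels population label per sample.
#' @return A list with the SS/df/MS table (`anova`), variance
#'   `components` and `percentages`, and `phi` (phi_st, phi_is, phi_it).
#' @export
amova <- function(gm, labels) {
  stopifnot_samples_match(gm, labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    drop_pop <- names(tab)[tab < 2]
    warning("excluding population(s) of size 1: ",
            paste(drop_pop, collapse = ", "))
    keep <- !(labels %in% drop_pop)
    gm <- gm[keep, ]; labels <- labels[keep]
  }
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("need at least two usable populations")
  d <- gm$dosage
  x <- d / 2  # individual mean allele value
  ss_ap <- 0; ss_ai <- 0; ss_wi <- 0
  df_ap <- 0; df_ai <- 0; df_wi <- 0
  nc_num <- 0; nc_den <- 0
  for (l in seq_len(ncol(d))) {
    xl <- x[, l]
    ok <- !is.na(xl)
    if (sum(ok) < 2) next
    lab <- labels[ok]; xv <- xl[ok]
    tabl <- table(lab)
    if (length(tabl) < 2) next
    grand <- mean(xv)
    pop_mean <- tapply(xv, lab, mean)
    n_i <- as.numeric(tabl)
    N <- sum(n_i); r <- length(n_i)
    ss_ap <- ss_ap + sum(2 * n_i * (pop_mean - grand)^2)
    ss_ai <- ss_ai + sum(2 * (xv - pop_mean[lab])^2)
    ss_wi <- ss_wi + sum(ifelse(d[ok, l] == 1L, 0.5, 0))
    df_ap <- df_ap + (r - 1)
    df_ai <- df_ai + (N - r)
    df_wi <- df_wi + N
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    nc_num <- nc_num + nc * (r - 1); nc_den <- nc_den + (r - 1)
  }
  if (df_ap == 0) stop("no locus with data in two or more populations")
  ms_ap <- ss_ap / df_ap; ms_ai <- ss_ai / df_ai; ms_wi <- ss_wi / df_wi
  n_c <- nc_num / nc_den
  sig_wi <- ms_wi
  sig_ai <- (ms_ai - ms_wi) / 2
  sig_ap <- (ms_ap - ms_ai) / (2 * n_c)
  comp <- pmax(c(among_pops = sig_ap, among_ind_within = sig_ai,
                 within_ind = sig_wi), 0)
  pct <- 100 * comp / sum(comp)
  phi_st <- comp[1] / sum(comp)
  phi_is <- if (comp[2] + comp[3] > 0) comp[2] / (comp[2] + comp[3]) else NA
  phi_it <- (comp[1] + comp[2]) / sum(comp)
  list(anova = data.frame(
         level = c("among_pops", "among_ind_within", "within_ind"),
         df = c(df_ap, df_ai, df_wi), SS = c(ss_ap, ss_ai, ss_wi),
         MS = c(ms_ap, ms_ai, ms_wi)),
       components = comp, percentages = pct,
       phi = c(phi_st = unname(phi_st), phi_is = unname(phi_is),
               phi_it = unname(phi_it)))
}

#' Pairwise kinship matrix
#'
#' Correlation-type kinship estimator on allele dosages:
#' \deqn{F_{ij} = \frac{\sum_l (x_{il} - \hat p_l)(x_{jl} - \hat p_l)}
#'                     {\sum_l \hat p_l (1 - \hat p_l)}}
#' with \eqn{x = } dosage/2 and \eqn{\hat p_l} the panel ALT frequency.
#' Negative off-diagonal values — pairs less related than random draws
#' from the panel — are truncated to zero.
#'
#' @param gm a [geno_matrix()] with no missing calls (impute first), or
#'   missing calls are mean-substituted per locus (which shrinks the
#'   affected pair terms toward zero).
#' @return Symmetric samples x samples matrix of class `matrix`.
#' @export
kinship_matrix <- function(gm) {
  d <- gm$dosage
  if (nrow(d) < 2) stop("need at least two samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci: kinship denominator is zero")
  x <- d[, poly, drop = FALSE] / 2
  pc <- p[poly]
  xc <- sweep(x, 2, pc)
  xc[is.na(xc)] <- 0
  K <- tcrossprod(xc) / sum(pc * (1 - pc))
  off <- K < 0
  diag(off) <- FALSE
  K[off] <- 0
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}
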