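test_that("composite r2 hits 1 for duplicated and repulsion columns", {
  set.seed(3)
  x <- rbinom(200, 2, 0.5)
  d <- cbind(x, x, 2L - x, rbinom(200, 2, 0.5))
  pairs <- pairwise_r2(gm_of(d), vt_of(c(100, 200, 300, 400)))
  get <- function(i, j) pairs$r2[pairs$i == i & pairs$j == j]
  expect_equal(get(1, 2), 1)
  expect_equal(get(1, 3), 1)   # perfect repulsion: |corr| = 1
  expect_lt(get(1, 4), 0.1)
  expect_true(all(pairs$p_value[pairs$r2 == 1] < 1e-10))
})

test_that("independent loci show r2 at the 1/N sampling-noise level", {
  set.seed(11)
  N <- 500
  d <- matrix(rbinom(N * 60, 2, 0.5), N, 60)
  pairs <- pairwise_r2(gm_of(d), vt_of(seq_len(60) * 1000))
  expect_lt(mean(pairs$r2), 3 / N)
  expect_gt(mean(pairs$r2), 0.2 / N)
})

test_that("pair tables respect the physical window", {
  p <- small_panel(seed = 7, loci = 100, chrom_length = 2e6)
  pairs <- pairwise_r2(p$genotypes, p$variants, window_bp = 1e5)
  expect_true(all(pairs$dist_bp <= 1e5 & pairs$dist_bp > 0))
})

test_that("decay distance follows the first-bin-below-threshold rule", {
  mk_pairs <- function(dists, r2s) {
    data.frame(i = seq_along(dists), j = seq_along(dists) + 1L,
               chrom = "B1", pos_i = 0L, pos_j = dists, dist_bp = dists,
               r2 = r2s, n = 100L, p_value = 0.001)
  }
  # bin means 0.5, 0.3, 0.09 -> decay at the third bin edge, 50 kb
  pairs <- mk_pairs(c(10e3, 30e3, 60e3), c(0.5, 0.3, 0.09))
  dec <- ld_decay(pairs, bin_bp = 25e3, r2_threshold = 0.1)
  expect_equal(dec$decay_distance_bp, 50e3)
  # never below threshold: NA sentinel (the extreme-LD subpopulation case)
  hi <- mk_pairs(c(10e3, 30e3, 60e3), c(0.5, 0.4, 0.3))
  expect_true(is.na(ld_decay(hi, 25e3, 0.1)$decay_distance_bp))
  # insignificant pairs are excluded
  pairs$p_value <- 0.5
  expect_warning(dec0 <- ld_decay(pairs), "no significant pairs")
  expect_true(is.na(dec0$decay_distance_bp))
})

test_that("decay distance is monotone in the r2 threshold", {
  # a lower critical r2 can only push the decay distance further out
  set.seed(13)
  dists <- rep(c(5e3, 30e3, 55e3, 80e3, 105e3), each = 20)
  r2s <- pmax(0.5 * exp(-dists / 3e4) + rnorm(100, 0, 0.02), 0)
  pairs <- data.frame(i = 1, j = 2, chrom = "B1", pos_i = 0L,
                      pos_j = dists, dist_bp = dists, r2 = r2s, n = 100L,
                      p_value = 0.01)
  thr <- c(0.05, 0.1, 0.2, 0.4)
  dd <- vapply(thr, function(t) {
    d <- ld_decay(pairs, 25e3, t)$decay_distance_bp
    if (is.na(d)) Inf else d
  }, 0)
  expect_true(all(diff(dd) <= 0))
})

test_that("D' point estimates and CIs behave at the extremes", {
  # complete coupling: only AB / ab haplotypes
  x <- rep(c(0L, 2L), each = 250)
  res <- dprime_ci(x, x)
  expect_equal(res$dprime, 1)
  expect_gte(res$ci_low, 0.9)
  expect_gte(res$ci_high, 0.98)
  # exact equilibrium at MAF 0.5, n = 500
  set.seed(17)
  a <- rbinom(500, 2, 0.5); b <- rbinom(500, 2, 0.5)
  res2 <- dprime_ci(a, b)
  expect_lt(res2$dprime, 0.2)
  expect_lt(res2$ci_high, 0.9)
  # five samples cannot pin D' down
  res3 <- dprime_ci(c(0L, 1L, 2L, 1L, 0L), c(1L, 0L, 2L, 1L, 0L))
  expect_gt(res3$ci_high - res3$ci_low, 0.5)
  expect_error(dprime_ci(rep(0L, 5), c(0L, 1L, 2L, 1L, 0L)),
               "polymorphic")
})

test_that("EM haplotype frequencies match truth on phased simulations", {
  # build genotypes from known haplotypes and compare r2 routes
  set.seed(19)
  for (rep in 1:20) {
    pA <- runif(1, 0.2, 0.8); pB <- runif(1, 0.2, 0.8)
    d_raw <- runif(1, -0.8, 0.8) *
      min(pA * (1 - pB), (1 - pA) * pB, pA * pB, (1 - pA) * (1 - pB))
    f <- c(ab = (1 - pA) * (1 - pB) + d_raw, aB = (1 - pA) * pB - d_raw,
           Ab = pA * (1 - pB) - d_raw, AB = pA * pB + d_raw)
    h <- sample(4, 2 * 500, replace = TRUE, prob = f)
    hap_a <- as.integer(h %in% c(3, 4)); hap_b <- as.integer(h %in% c(2, 4))
    g_a <- hap_a[1:500] + hap_a[501:1000]
    g_b <- hap_b[1:500] + hap_b[501:1000]
    # true haplotypic r2 from the phased data
    r_hap <- suppressWarnings(cor(hap_a, hap_b))
    if (!is.finite(r_hap)) next
    r_comp <- suppressWarnings(cor(g_a, g_b))
    expect_lt(abs(r_comp^2 - r_hap^2), 0.05)
  }
})

test_that("Gabriel blocks match brute-force enumeration on small instances", {
  brute_blocks <- function(dp, vt) {
    strong <- dp$ci_low >= 0.70 & dp$ci_high >= 0.98
    recomb <- dp$ci_high < 0.90
    inform <- strong | recomb
    m <- nrow(vt)
    cands <- list()
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      e <- which(dp$i == i & dp$j == j)
      if (!length(e) || !strong[e]) next
      inside <- dp$i >= i & dp$j <= j
      n_inf <- sum(inform & inside)
      if (n_inf == 0 || sum(strong & inside) / n_inf < 0.95) next
      cands[[length(cands) + 1L]] <- c(i, j)
    }
    if (!length(cands)) return(NULL)
    cands <- do.call(rbind, cands)
    span <- vt$pos[cands[, 2]] - vt$pos[cands[, 1]]
    cands <- cands[order(-span, vt$pos[cands[, 1]]), , drop = FALSE]
    picked <- NULL
    for (r in seq_len(nrow(cands))) {
      ok <- TRUE
      if (!is.null(picked))
        for (q in seq_len(nrow(picked)))
          if (cands[r, 1] <= picked[q, 2] && cands[r, 2] >= picked[q, 1])
            ok <- FALSE
      if (ok) picked <- rbind(picked, cands[r, , drop = FALSE])
    }
    picked[order(picked[, 1]), , drop = FALSE]
  }
  set.seed(23)
  for (rep in 1:6) {
    m <- sample(5:12, 1)
    base <- rbinom(300, 2, 0.5)
    d <- sapply(seq_len(m), function(k) {
      if (runif(1) < 0.5) {
        flip <- runif(300) < 0.03          # near-copies: strong LD
        out <- base; out[flip] <- rbinom(sum(flip), 2, 0.5); out
      } else rbinom(300, 2, runif(1, 0.2, 0.8))
    })
    vt <- vt_of(seq_len(m) * 1e4)
    dp <- ld_dprime(gm_of(d), vt, window_bp = 5e5)
    got <- gabriel_blocks(dp, vt)
    want <- brute_blocks(dp, vt)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$first, unname(want[, 1]))
      expect_equal(got$last, unname(want[, 2]))
    }
  }
})

test_that("block detection handles canonical configurations", {
  set.seed(29)
  x <- rbinom(500, 2, 0.5)
  # two perfectly linked SNPs -> one block of 2
  d <- cbind(x, x)
  vt <- vt_of(c(1000, 3000))
  bl <- gabriel_blocks(ld_dprime(gm_of(d), vt), vt)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$n_snps, 2L)
  expect_equal(bl$size_kb, 2)
  # all pairs in strong recombination -> no blocks
  d2 <- sapply(1:5, function(k) rbinom(500, 2, 0.5))
  vt2 <- vt_of(1:5 * 1000)
  expect_equal(nrow(gabriel_blocks(ld_dprime(gm_of(d2), vt2), vt2)), 0)
  # three mutually strong loci plus two independents -> one block 1..3
  d3 <- cbind(x, x, x, rbinom(500, 2, 0.5), rbinom(500, 2, 0.5))
  vt3 <- vt_of(1:5 * 1000)
  bl3 <- gabriel_blocks(ld_dprime(gm_of(d3), vt3), vt3)
  expect_equal(nrow(bl3), 1)
  expect_equal(c(bl3$first, bl3$last), c(1L, 3L))
})

test_that("planted sweeps raise D' and strong-LD pair density locally", {
  hits <- 0
  for (seed in 1:10) {
    p <- small_panel(seed = seed + 300, n_per_pop = c(60, 60), fst = 0.05,
                     chrom_length = 2e6, loci = 120, selfing = 0.8,
                     missing = 0,
                     sweeps = list(sweep_spec("B1", 5e5, 1.5e6, 2, 0.95)))
    flt <- filter_snps(p$genotypes, p$variants)
    dp <- ld_dprime(flt$genotypes, flt$variants, window_bp = 5e5)
    inside <- dp$pos_i >= 5e5 & dp$pos_j <= 1.5e6
    if (sum(inside) < 10 || sum(!inside) < 10) next
    if (mean(dp$dprime[inside]) > mean(dp$dprime[!inside])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("marker budget arithmetic reproduces the printed bounds", {
  expect_equal(min_markers_for_gwas(1284000, 700), 1834L)
  expect_equal(min_markers_for_gwas(1544000, 700), 2206L)
  expect_equal(min_markers_for_gwas(1000, 100), 10L)
  expect_error(min_markers_for_gwas(-1, 100), "positive")
})
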