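test_that("allele statistics match hand calculations", {
  # p = 0.5 with all heterozygotes
  gm <- gm_of(cbind(rep(1L, 10), rep(0L, 10), c(rep(0L, 5), rep(2L, 5))))
  st <- allele_stats(gm)
  expect_equal(st$he[1], 0.5)
  expect_equal(st$pic[1], 0.375)   # 0.5 - 2 * 0.25 * 0.25
  expect_equal(st$ho[1], 1)
  expect_equal(st$he[2], 0)        # monomorphic
  expect_equal(st$pic[2], 0)
  expect_equal(st$he[3], 0.5)
  expect_equal(st$ho[3], 0)
})

test_that("PIC never exceeds He", {
  p <- small_panel(seed = 41, loci = 300)
  st <- allele_stats(p$genotypes)
  ok <- !is.na(st$he)
  expect_true(all(st$pic[ok] <= st$he[ok] + 1e-12))
  poly <- ok & st$maf > 0
  expect_true(all(st$pic[poly] < st$he[poly]))
})

test_that("windowed pi matches simple pairwise counts", {
  # one diploid sample = two pseudo-haplotypes differing at its het sites
  gm <- gm_of(matrix(c(1L, 1L, 1L, 0L, 2L), nrow = 1))
  vt <- vt_of(c(100, 200, 300, 400, 500))
  wd <- windowed_diversity(gm, vt, window = 1e5)
  expect_equal(wd$pi, 3e-5)        # 3 differing sites / 100 kb
  expect_equal(wd$S, 3L)
  expect_equal(wd$tajima_d, 0)     # n = 2 identity
})

test_that("Watterson's theta uses the harmonic number at the window n", {
  # 2 diploids (n = 4), 5 segregating sites in a 1-kb window
  d <- rbind(c(1L, 1L, 1L, 1L, 1L),
             c(0L, 1L, 2L, 0L, 1L))
  wd <- windowed_diversity(gm_of(d), vt_of(c(10, 20, 30, 40, 50)),
                           window = 1000)
  expect_equal(wd$S, 5L)
  expect_equal(wd$theta_w, 5 / ((1 + 1 / 2 + 1 / 3) * 1000),
               tolerance = 1e-12)
})

test_that("windowed mean pairwise differences equal brute-force enumeration", {
  # oracle: per site, expand to 2n pseudo-haplotypes (a ALT copies) and
  # average |h_i - h_j| over every haplotype pair by explicit double loop
  brute_k <- function(d) {
    total <- 0
    for (l in seq_len(ncol(d))) {
      g <- d[, l]; g <- g[!is.na(g)]
      if (!length(g)) next
      h <- c(rep(1L, sum(g)), rep(0L, 2 * length(g) - sum(g)))
      s <- 0; np <- 0
      for (i in seq_along(h)) for (j in seq_along(h)) if (i < j) {
        s <- s + abs(h[i] - h[j]); np <- np + 1
      }
      total <- total + s / np
    }
    total
  }
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:20, 1); L <- sample(10:50, 1)
    d <- matrix(rbinom(n * L, 2, runif(L, 0.1, 0.9)[rep(1:L, each = n)]),
                n, L)
    wd <- windowed_diversity(gm_of(d), vt_of(seq_len(L) * 10),
                             window = 1e5)
    expect_equal(wd$pi * 1e5, brute_k(d), tolerance = 1e-10)
  }
})

test_that("planted sweeps depress Tajima's D in the target population", {
  hits <- 0
  for (seed in 1:20) {
    p <- small_panel(seed = seed + 100, n_per_pop = c(30, 60), fst = 0.05,
                     chrom_length = 2e6, loci = 150, selfing = 0.8,
                     missing = 0,
                     sweeps = list(sweep_spec("B1", 5e5, 1e6, 2, 0.95)))
    sp2 <- p$truth$pops$pop == "SP2"
    wd <- windowed_diversity(p$genotypes[sp2, ], p$variants, window = 1e5)
    wd <- wd[!is.na(wd$tajima_d), ]
    in_sweep <- wd$start >= 5e5 & wd$end <= 1e6
    if (!any(in_sweep)) next
    if (mean(wd$tajima_d[in_sweep]) < median(wd$tajima_d)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Weir-Cockerham F_ST hits the algebraic extremes", {
  # populations fixed for alternate alleles
  d <- rbind(matrix(0L, 10, 20), matrix(2L, 10, 20))
  labels <- rep(c("A", "B"), each = 10)
  expect_equal(weir_cockerham_fst(gm_of(d), labels)$fst, 1)
  # identical genotype tables: no differentiation, estimate may be <= 0
  set.seed(8)
  block <- matrix(rbinom(10 * 50, 2, 0.4), 10, 50)
  d2 <- rbind(block, block)
  expect_lte(weir_cockerham_fst(gm_of(d2), labels)$fst, 0)
  expect_error(weir_cockerham_fst(gm_of(d), rep("A", 20)), "two populations")
  expect_error(weir_cockerham_fst(gm_of(d), rep("A", 3)), "labels")
})

test_that("per-locus and windowed F_ST agree with the multilocus ratio", {
  p <- small_panel(seed = 55, loci = 200, missing = 0.05)
  labels <- p$truth$pops$pop
  per <- weir_cockerham_fst(p$genotypes, labels, mode = "per_locus")
  expect_length(per, nrow(p$variants))
  win <- weir_cockerham_fst(p$genotypes, labels, mode = "windowed",
                            vt = p$variants, window = 1e9)
  ml <- weir_cockerham_fst(p$genotypes, labels)$fst
  # one giant window = the multilocus ratio-of-sums
  expect_equal(win$fst[1], ml, tolerance = 1e-12)
  pw <- weir_cockerham_fst(p$genotypes, labels, mode = "pairwise_pops")
  expect_equal(pw$fst[1], ml, tolerance = 1e-12)
})

test_that("AMOVA partitions variance as expected", {
  labels <- rep(c("A", "B"), each = 10)
  # fixed differences: everything among populations
  d <- rbind(matrix(0L, 10, 30), matrix(2L, 10, 30))
  am <- amova(gm_of(d), labels)
  expect_equal(unname(am$percentages["among_pops"]), 100)
  expect_equal(sum(am$percentages), 100, tolerance = 1e-9)
  # permuted labels: among-population component collapses
  p <- small_panel(seed = 61, n_per_pop = c(100, 100), loci = 300,
                   missing = 0)
  set.seed(3)
  perm <- sample(p$truth$pops$pop)
  am2 <- amova(p$genotypes, perm)
  expect_lt(am2$percentages["among_pops"], 2)
  expect_equal(sum(am2$percentages), 100, tolerance = 1e-9)
  d3 <- rbind(d, d[1, , drop = FALSE])
  expect_warning(amova(gm_of(d3), c(labels, "C")), "size 1")
})

test_that("AMOVA on an inbred two-population panel mirrors its F-statistics", {
  p <- small_panel(seed = 71, loci = 250, missing = 0)
  labels <- p$truth$pops$pop
  am <- amova(p$genotypes, labels)
  wc <- weir_cockerham_fst(p$genotypes, labels)
  expect_equal(unname(am$phi["phi_st"]), wc$fst, tolerance = 0.05)
  # strong inbreeding: low within-individual share, high phi_it
  expect_lt(unname(am$percentages["within_ind"]), 30)
  expect_gt(unname(am$phi["phi_it"]), wc$fst)
})

test_that("kinship recovers duplicates, strangers, and parent-offspring", {
  set.seed(77)
  L <- 5000
  p <- runif(L, 0.1, 0.9)
  unrel <- matrix(rbinom(40 * L, 2, rep(p, each = 40)), 40, L)
  parent <- unrel[1, ]
  # offspring: one gamete from the parent, one from the population
  from_parent <- rbinom(L, 1, parent / 2)
  offspring <- from_parent + rbinom(L, 1, p)
  dup <- unrel[2, ]
  d <- rbind(unrel, offspring, dup)
  rownames(d) <- c(sprintf("U%02d", 1:40), "off", "dup")
  K <- kinship_matrix(gm_of(d))
  # duplicated sample dominates its row
  off_diag <- K["dup", setdiff(rownames(d), "dup")]
  expect_equal(names(which.max(off_diag)), "U02")
  expect_gt(K["dup", "U02"], 0.4)
  # parent-offspring near 0.25
  expect_lt(abs(K["off", "U01"] - 0.25), 0.05)
  # unrelated pairs are truncated at zero and small
  expect_true(all(K[upper.tri(K)] >= 0))
  expect_lt(median(K[upper.tri(K)]), 0.02)
  expect_error(kinship_matrix(gm_of(matrix(2L, 5, 10))), "polymorphic")
})
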