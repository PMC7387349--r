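mini_vcf <- function(lines, dir = withr::local_tempdir(
                       .local_envir = parent.frame())) {
  path <- file.path(dir, "mini.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("VCF genotypes and depths parse to dosage/depth", {
  path <- mini_vcf(c(vcf_header(),
                     "B1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:12\t./.:0",
                     "B1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1/1:8\t0/0:4",
                     "B1\t300\t.\tG\tGA\t.\tPASS\t.\tGT:DP\t0/1:9\t0/0:7",
                     "B1\t400\t.\tT\tA,C\t.\tPASS\t.\tGT:DP\t0/1:9\t0/0:7"))
  v <- suppressMessages(read_vcf(path))
  expect_equal(v$n_skipped, 2)  # indel + multi-allelic dropped
  expect_equal(dim(v$genotypes$dosage), c(2L, 2L))
  expect_equal(unname(v$genotypes$dosage["S1", ]), c(1L, 2L))
  expect_equal(unname(v$genotypes$depth["S1", ]), c(12L, 8L))
  expect_true(is.na(v$genotypes$dosage["S2", 1]))
  expect_equal(unname(v$genotypes$depth["S2", 1]), 0L)
})

test_that("malformed VCF lines are reported with their line number", {
  path <- mini_vcf(c(vcf_header(),
                     "B1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:12\t0/0:9",
                     "B1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1/1:8"))
  expect_error(read_vcf(path), "line 6")
  empty <- mini_vcf(vcf_header())
  expect_error(read_vcf(empty), "zero usable records")
})

test_that("VCF without DP leaves depth unknown and depth filter inactive", {
  path <- mini_vcf(c(vcf_header(),
                     "B1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
                     "B1\t250\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1"))
  v <- read_vcf(path)
  expect_true(all(is.na(v$genotypes$depth)))
  flt <- filter_snps(v$genotypes, v$variants, maf_min = 0, het_max = 1,
                     depth_min = 4, missing_max = 1)
  expect_equal(flt$report$count[flt$report$rule == "depth_masked_calls"], 0)
  expect_equal(ncol(flt$genotypes$dosage), 2L)
})

test_that("filter thresholds follow the quoted boundary semantics", {
  # 50 samples; engineer per-locus MAF / het / missingness
  n <- 50
  mk <- function(n0, n1, n2, nna = 0) {
    c(rep(0L, n0), rep(1L, n1), rep(2L, n2), rep(NA, nna))
  }
  d <- cbind(
    maf04 = mk(46, 4, 0),          # MAF 0.04 -> removed (strict > 0.05)
    maf05 = mk(45, 5, 0),          # MAF 0.05 -> removed (boundary excluded)
    maf06 = mk(45, 4, 1),          # MAF 0.06, het 0.08 -> retained
    het12 = mk(38, 6, 6),          # het 0.12 -> removed
    het10 = mk(39, 5, 6),          # het 0.10 -> retained (inclusive)
    mis32 = mk(26, 3, 5, 16),      # 32% missing -> removed
    mis30 = mk(27, 3, 5, 15)       # 30% missing -> retained ("up to")
  )
  gm <- gm_of(d)
  vt <- vt_of(seq_len(ncol(d)) * 1000)
  flt <- filter_snps(gm, vt, maf_min = 0.05, het_max = 0.1, depth_min = 0,
                     missing_max = 0.30)
  expect_setequal(colnames(flt$genotypes$dosage),
                  c("maf06", "het10", "mis30"))
  expect_equal(flt$variants$missing_rate[flt$variants$snp_name ==
                                           vt$snp_name[7]], 0.30)
  rep <- flt$report
  expect_equal(rep$count[rep$rule == "low_maf"], 2)
  expect_equal(rep$count[rep$rule == "high_heterozygosity"], 1)
  expect_equal(rep$count[rep$rule == "high_missingness"], 1)
})

test_that("depth masking precedes the locus filters", {
  d <- rbind(c(0L, 1L), c(2L, 1L), c(1L, 1L), c(2L, 0L))
  dp <- rbind(c(3L, 10L), c(10L, 10L), c(10L, 10L), c(10L, 10L))
  gm <- geno_matrix(d, dp)
  vt <- vt_of(c(1000, 2000))
  flt <- filter_snps(gm, vt, maf_min = 0, het_max = 1, depth_min = 4,
                     missing_max = 1)
  expect_equal(flt$report$count[flt$report$rule == "depth_masked_calls"], 1)
  expect_true(is.na(flt$genotypes$dosage[1, 1]))
  # masked call no longer counts toward locus statistics
  expect_equal(flt$variants$missing_rate[1], 0.25)
})

test_that("filtering is idempotent", {
  p <- small_panel(seed = 17, missing = 0.15)
  f1 <- filter_snps(p$genotypes, p$variants)
  f2 <- filter_snps(f1$genotypes, f1$variants)
  expect_identical(f1$genotypes$dosage, f2$genotypes$dosage)
  expect_equal(f2$report$count[f2$report$rule != "retained"],
               rep(0, 4))
})

test_that("imputation draws from observed frequencies and is deterministic", {
  d <- cbind(rep(2L, 10), c(rep(0L, 5), rep(2L, 5)))
  d[1:3, 1] <- NA; d[1:2, 2] <- NA
  gm <- gm_of(d)
  out1 <- impute_missing(gm, seed = 5)
  out2 <- impute_missing(gm, seed = 5)
  expect_identical(out1$dosage, out2$dosage)
  expect_false(anyNA(out1$dosage))
  # observed frequency 1.0 -> every imputed call is dosage 2
  expect_true(all(out1$dosage[1:3, 1] == 2L))
  # observed calls never altered
  expect_identical(out1$dosage[4:10, 1], gm$dosage[4:10, 1])
  # complete matrix returned unchanged
  full <- gm_of(matrix(1L, 4, 3))
  expect_identical(impute_missing(full, seed = 1), full)
  # all-missing locus cannot be imputed
  bad <- gm_of(cbind(c(NA, NA, NA), c(0L, 1L, 2L)))
  expect_error(impute_missing(bad, seed = 1), "zero observed calls")
})

test_that("hold-out imputation beats the p = 0.5 concordance floor", {
  p <- small_panel(seed = 23, n_per_pop = c(80, 80), fst = 0.05,
                   loci = 400, selfing = 0.5, missing = 0)
  d <- p$genotypes$dosage
  set.seed(42)
  mask <- which(matrix(runif(length(d)) < 0.05, nrow(d)))
  truth <- d[mask]
  d[mask] <- NA
  imp <- impute_missing(gm_of(d), seed = 9)
  concordance <- mean(imp$dosage[mask] == truth)
  expect_gt(concordance, 0.375)
})

test_that("site context classes partition the loci", {
  p <- small_panel(seed = 29, chrom_length = 3e5, loci = 120)
  vt <- annotate_sites(p$variants, p$annotation)
  expect_true(all(vt$context %in% c("coding", "intron", "intergenic")))
  expect_equal(sum(table(vt$context)), nrow(vt))
})

test_that("context assignment matches hand-placed intervals", {
  seq <- paste(rep("ACGT", 250), collapse = "")  # 1000 bp
  cds <- rbind(cds_row("g1", 101, 160, "+", 0L),
               cds_row("g1", 201, 260, "+", 0L),
               cds_row("g2", 501, 560, "-", 0L))
  ann <- ann_of(seq, cds)
  vt <- vt_of(c(130, 180, 400, 530, 540))
  vt <- annotate_sites(vt, ann)
  expect_equal(vt$context, c("coding", "intron", "intergenic",
                             "coding", "coding"))
  # intron of the minus-strand gene is still intron
  cds2 <- rbind(cds_row("g3", 601, 660, "-", 0L),
                cds_row("g3", 701, 760, "-", 2L))
  ann2 <- ann_of(seq, rbind(cds, cds2))
  vt2 <- annotate_sites(vt_of(680), ann2)
  expect_equal(vt2$context, "intron")
  expect_error(annotate_sites(vt_of(10, chrom = "Z1"), ann),
               "absent from annotation")
})

test_that("coding effects follow the standard genetic code", {
  # plus strand: codons GGT (Gly) then ATG (Met) starting at 11
  seq <- paste0(strrep("T", 10), "GGTATGCCC", strrep("A", 81))
  ann <- ann_of(seq, cds_row("g1", 11, 19, "+", 0L))
  vt <- variant_table(rep("B1", 2), c(13, 16), c("T", "G"), c("C", "A"))
  vt <- annotate_sites(vt, ann)
  vt <- classify_coding_effect(vt, ann)
  expect_equal(vt$effect, c("synonymous", "non-synonymous"))  # GGT>GGC, ATG>ATA
})

test_that("minus-strand effects are computed on the transcript strand", {
  # minus strand CDS 21..29; transcript = revcomp(genomic)
  genomic <- paste0(strrep("A", 20), "CATGGCCAT", strrep("G", 71))
  # transcript codons: revcomp("CATGGCCAT") = ATGGCCATG -> Met Ala Met
  ann <- ann_of(genomic, cds_row("g1", 21, 29, "-", 0L))
  # genomic C>T at 26 reads as G>A on the transcript: GCC -> ACC (Ala>Thr)
  vt <- variant_table("B1", 26, "C", "T")
  vt <- annotate_sites(vt, ann)
  vt <- classify_coding_effect(vt, ann)
  expect_equal(vt$effect, "non-synonymous")
  # genomic G>A at 24 is the codon's third position: GCC -> GCT, still Ala
  vt2 <- classify_coding_effect(annotate_sites(
    variant_table("B1", 24, "G", "A"), ann), ann)
  expect_equal(vt2$effect, "synonymous")
  expect_error(classify_coding_effect(annotate_sites(
    variant_table("B1", 26, "G", "T"), ann), ann), "disagrees")
})

test_that("effects are invariant under reverse-complementing the reference", {
  p <- small_panel(seed = 37, chrom_length = 2e5, loci = 80, missing = 0)
  vt <- classify_coding_effect(annotate_sites(p$variants, p$annotation),
                               p$annotation)
  ann <- p$annotation
  len <- Biostrings::width(ann$seq)[1]
  rc_seq <- Biostrings::reverseComplement(ann$seq)
  names(rc_seq) <- names(ann$seq)
  flip <- function(df) {
    new <- df
    new$start <- len - df$end + 1L
    new$end <- len - df$start + 1L
    new$strand <- ifelse(df$strand == "+", "-", "+")
    new[order(new$chrom, new$start), , drop = FALSE]
  }
  ann_rc <- genome_annotation(rc_seq, flip(ann$genes),
                              flip(ann$cds), flip(ann$exons))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vt_rc <- variant_table(p$variants$chrom,
                         sort(len - p$variants$pos + 1L),
                         comp[p$variants$ref[nrow(p$variants):1]],
                         comp[p$variants$alt[nrow(p$variants):1]])
  vt_rc <- classify_coding_effect(annotate_sites(vt_rc, ann_rc), ann_rc)
  expect_equal(rev(vt_rc$effect), vt$effect)
  expect_equal(rev(vt_rc$context), vt$context)
})
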