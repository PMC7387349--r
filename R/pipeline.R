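#' Pipeline configuration
#'
#' Collects every stage parameter with the panel-analysis defaults (MAF
#' > 0.05, heterozygosity <= 0.1, depth >= 4, missing <= 30%, 100-kb
#' diversity/F_ST windows, 500-kb LD window, 25-kb decay bins, critical
#' r-squared 0.1, Q threshold 0.70, loading threshold 0.02, 400-kb block
#' floor). Exactly one input source must be given: either a VCF (plus
#' population table, and optionally GFF3 + FASTA for annotation) or a
#' simulation configuration.
#'
#' @param vcf,pops,gff,fasta input file paths (VCF mode).
#' @param sim a [sim_config()] (simulation mode).
#' @param out_dir output directory.
#' @param seed integer; fans out to per-stage seeds.
#' @param maf_min,het_max,depth_min,missing_max SNP filters.
#' @param window diversity/F_ST window (bp).
#' @param ld_window_bp LD pair window (bp).
#' @param bin_bp LD decay bin (bp).
#' @param r2_critical critical r-squared for decay and pruning.
#' @param q_threshold membership assignment threshold.
#' @param k_range,k_replicates delta-K model-selection grid.
#' @param loading_threshold,fst_z,min_block_kb,min_evidence sweep-scan
#'   parameters.
#' @param run_sweep_scan set `FALSE` to skip the (relatively expensive)
#'   D'/block and sweep-integration stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, pops = NULL, gff = NULL,
                            fasta = NULL, sim = NULL, out_dir = "gbspopgen_out",
                            seed = 1L, maf_min = 0.05, het_max = 0.1,
                            depth_min = 4, missing_max = 0.30,
                            window = 1e5, ld_window_bp = 5e5,
                            bin_bp = 25000, r2_critical = 0.1,
                            q_threshold = 0.70, k_range = 1:5,
                            k_replicates = 3L, loading_threshold = 0.02,
                            fst_z = 3.0, min_block_kb = 400,
                            min_evidence = 2L, run_sweep_scan = TRUE) {
  if (is.null(vcf) == is.null(sim))
    stop("exactly one of a VCF input or a simulation config must be given")
  if (!is.null(vcf) && is.null(pops))
    stop("VCF input requires a sample-to-population table (pops)")
  for (p in c(maf_min, het_max, missing_max, q_threshold,
              loading_threshold)) check_prob(p, "threshold")
  structure(list(vcf = vcf, pops = pops, gff = gff, fasta = fasta,
                 sim = sim, out_dir = out_dir, seed = as.integer(seed),
                 maf_min = maf_min, het_max = het_max,
                 depth_min = depth_min, missing_max = missing_max,
                 window = window, ld_window_bp = ld_window_bp,
                 bin_bp = bin_bp, r2_critical = r2_critical,
                 q_threshold = q_threshold, k_range = k_range,
                 k_replicates = k_replicates,
                 loading_threshold = loading_threshold, fst_z = fst_z,
                 min_block_kb = min_block_kb,
                 min_evidence = as.integer(min_evidence),
                 run_sweep_scan = isTRUE(run_sweep_scan)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat key namespace matching the arguments of [pipeline_config()];
#' simulation parameters live under a `sim:` mapping whose keys match
#' [sim_config()] (sweeps as a list of chrom/start/end/target_pop/
#' haplotype_fraction mappings).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    sweeps <- lapply(y$sim$sweeps, function(s)
      sweep_spec(s$chrom, s$start, s$end, s$target_pop %||% 2L,
                 s$haplotype_fraction %||% 0.9))
    sim_args <- y$sim[setdiff(names(y$sim), "sweeps")]
    y$sim <- do.call(sim_config, c(sim_args, list(sweep_specs = sweeps)))
  }
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full panel analysis pipeline
#'
#' Executes simulate/read -> filter -> impute -> annotate -> diversity
#' -> structure -> LD/blocks -> sweep scan, writing one TSV per product
#' into `cfg$out_dir` and returning a run report. Every stage draws its
#' seed deterministically from `cfg$seed`, so identical configurations
#' yield byte-identical output files.
#'
#' @param cfg a [pipeline_config()].
#' @return A list of class `run_report`: `counts` (per-stage record
#'   counts), `params` (parameter echo), `timings` (seconds per stage),
#'   `manifest` (file, md5), `files`, plus the in-memory `results`.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); counts <- c(); files <- character()
  results <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  # abort with the failing stage's name and the files written so far
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           if (length(files)) paste0("\npartial outputs: ",
                                     paste(basename(unlist(files)),
                                           collapse = ", ")),
           call. = FALSE)
    })
  }
  emit <- function(df, name) {
    files[[name]] <<- write_tsv(df, file.path(cfg$out_dir, name))
  }

  # --- input ---
  stage("input", {
    if (!is.null(cfg$sim)) {
      panel <- simulate_panel(cfg$sim)
      gm <- panel$genotypes; vt <- panel$variants
      ann <- panel$annotation
      pops <- panel$truth$pops
    } else {
      vin <- read_vcf(cfg$vcf)
      gm <- vin$genotypes; vt <- vin$variants
      pops <- utils::read.table(cfg$pops, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      ann <- if (!is.null(cfg$gff) && !is.null(cfg$fasta))
        read_annotation(cfg$gff, cfg$fasta) else NULL
      panel <- panel_bundle(gm, vt, ann,
                            truth = list(pops = pops, sweeps = NULL))
    }
    labels <- pops$pop[match(rownames(gm$dosage), pops$sample_id)]
    if (any(is.na(labels)))
      stop("population table does not cover all samples")
    counts["input_samples"] <- nrow(gm$dosage)
    counts["input_snps"] <- ncol(gm$dosage)
  })
  tick("input")

  # --- filter + impute ---
  stage("filter_impute", {
    flt <- filter_snps(gm, vt, cfg$maf_min, cfg$het_max, cfg$depth_min,
                       cfg$missing_max)
    gm <- flt$genotypes; vt <- flt$variants
    emit(flt$report, "filter_report.tsv")
    counts["filtered_snps"] <- ncol(gm$dosage)
    gmi <- impute_missing(gm, vt, seed = derive_seed(cfg$seed, 2L))
  })
  tick("filter_impute")

  # --- annotate ---
  stage("annotate", {
    if (!is.null(ann)) {
      vt <- annotate_sites(vt, ann)
      vt <- classify_coding_effect(vt, ann)
      counts["coding_snps"] <- sum(vt$context == "coding", na.rm = TRUE)
    }
    emit(vt, "variants.tsv")
  })
  tick("annotate")

  # --- diversity ---
  stage("diversity", {
    wd <- windowed_diversity(gm, vt, window = cfg$window)
    wfst <- weir_cockerham_fst(gm, labels, mode = "windowed", vt = vt,
                               window = cfg$window)
    wd$fst <- wfst$fst[match(paste(wd$chrom, wd$start),
                             paste(wfst$chrom, wfst$start))]
    emit(wd, "window_stats.tsv")
    scopes <- list(all = seq_len(nrow(vt)))
    subg <- substr(vt$chrom, 1, 1)
    for (sg in sort(unique(subg)))
      scopes[[paste0("subgenome_", sg)]] <- which(subg == sg)
    if (!is.null(ann) && any(!is.na(vt$context)))
      for (cx in c("coding", "intron", "intergenic"))
        scopes[[cx]] <- which(vt$context == cx)
    dsum <- do.call(rbind, lapply(names(scopes), function(s)
      diversity_summary(gm, vt, scopes[[s]], scope = s)))
    emit(dsum, "diversity_summary.tsv")
    am <- amova(gm, labels)
    emit(data.frame(level = names(am$components),
                    component = as.numeric(am$components),
                    percent = as.numeric(am$percentages)), "amova.tsv")
    mlf <- weir_cockerham_fst(gm, labels, mode = "multilocus")
    pwf <- weir_cockerham_fst(gm, labels, mode = "pairwise_pops")
    emit(pwf, "pairwise_fst.tsv")
    K <- kinship_matrix(gmi)
    emit(data.frame(sample_id = rownames(K), K, check.names = FALSE),
         "kinship.tsv")
    counts["windows"] <- nrow(wd)
  })
  tick("diversity")

  # --- structure ---
  stage("structure", {
    pruned <- ld_prune(gm, vt, r2_max = cfg$r2_critical,
                       window_bp = cfg$ld_window_bp)
    counts["pruned_snps"] <- length(pruned)
    gmp <- gmi[, pruned]
    ks <- select_k(gmp, k_range = cfg$k_range,
                   replicates = cfg$k_replicates,
                   seed = derive_seed(cfg$seed, 3L))
    emit(ks$table, "k_selection.tsv")
    Q <- ks$best_fit$Q
    member <- assign_membership(Q, cfg$q_threshold)
    emit(data.frame(sample_id = rownames(gm$dosage), Q, label = member,
                    check.names = FALSE), "qmatrix.tsv")
    pca <- run_pca(gmi)
    emit(data.frame(sample_id = rownames(gm$dosage),
                    pca$scores[, seq_len(min(5, ncol(pca$scores)))],
                    check.names = FALSE), "pca_scores.tsv")
    tree <- build_tree(gmi, method = "upgma",
                       seed = derive_seed(cfg$seed, 4L))
    tree_path <- file.path(cfg$out_dir, "tree.nwk")
    ape::write.tree(tree$tree, tree_path)
    files[["tree.nwk"]] <- tree_path
    counts["chosen_k"] <- ks$chosen_k
  })
  tick("structure")

  # --- LD ---
  stage("ld", {
    pairs <- pairwise_r2(gm, vt, window_bp = cfg$ld_window_bp)
    decay <- ld_decay(pairs, bin_bp = cfg$bin_bp,
                      r2_threshold = cfg$r2_critical)
    emit(decay$bins, "ld_decay.tsv")
    ld_rows <- list()
    add_ld_row <- function(scope, sel) {
      pr <- pairs[sel, , drop = FALSE]
      dc <- suppressWarnings(ld_decay(pr, bin_bp = cfg$bin_bp,
                                      r2_threshold = cfg$r2_critical))
      data.frame(scope = scope, n_pairs = nrow(pr),
                 mean_r2 = mean(pr$r2),
                 decay_kb = dc$decay_distance_bp / 1000)
    }
    ld_rows[["genome"]] <- add_ld_row("genome", seq_len(nrow(pairs)))
    for (sg in sort(unique(substr(pairs$chrom, 1, 1))))
      ld_rows[[paste0("subgenome_", sg)]] <-
        add_ld_row(paste0("subgenome_", sg),
                   which(substr(pairs$chrom, 1, 1) == sg))
    for (ch in sort(unique(pairs$chrom)))
      ld_rows[[ch]] <- add_ld_row(ch, which(pairs$chrom == ch))
    emit(do.call(rbind, ld_rows), "ld_summary.tsv")
    counts["ld_pairs"] <- nrow(pairs)
  })
  tick("ld")

  # --- blocks + sweep scan ---
  roi <- NULL
  if (cfg$run_sweep_scan) stage("sweep", {
    dp <- ld_dprime(gm, vt, window_bp = cfg$ld_window_bp)
    blocks <- gabriel_blocks(dp, vt)
    emit(blocks, "blocks.tsv")
    counts["blocks"] <- nrow(blocks)
    lr <- loading_regions(pca, vt, threshold = cfg$loading_threshold,
                          gap_bp = cfg$ld_window_bp)
    runs <- tryCatch(fst_outlier_windows(wfst, z = cfg$fst_z),
                     error = function(e) NULL)
    roi <- integrate_roi(lr, runs, blocks,
                         min_block_kb = cfg$min_block_kb,
                         min_evidence = cfg$min_evidence)
    if (nrow(roi)) {
      extra <- lapply(seq_len(nrow(roi)), function(r)
        regional_pca(gmi, vt, roi[r, ], labels))
      roi$n_snps <- vapply(extra, `[[`, 0, "n_snps")
      roi$var_pc2 <- vapply(extra, `[[`, 0, "var_pc2")
      roi$var_pc5 <- vapply(extra, `[[`, 0, "var_pc5")
      roi$silhouette <- vapply(extra, `[[`, 0, "silhouette")
    }
    emit(as.data.frame(roi), "roi.tsv")
    if (!is.null(ann) && nrow(roi))
      emit(genes_in_regions(as.data.frame(roi), ann), "roi_genes.tsv")
    counts["roi"] <- nrow(roi)
    tick("sweep")
  })

  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  report <- structure(list(counts = counts,
                           params = cfg[!names(cfg) %in% c("sim")],
                           timings = unlist(timings),
                           manifest = manifest,
                           files = unlist(files),
                           results = list(
                             variants = vt, window_stats = wd,
                             diversity = dsum, amova = am,
                             fst = mlf, pairwise_fst = pwf,
                             k_selection = ks, membership = member,
                             decay = decay, roi = roi)),
                      class = "run_report")
  report
}

#' Write the run report to disk
#'
#' Writes the file manifest (name + checksum) and a short human-readable
#' summary of record counts, parameters and timings.
#'
#' @param report a `run_report` from [run_full()].
#' @param dir output directory (defaults to where the run wrote its
#'   files).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, dir = dirname(report$files[1])) {
  stopifnot(inherits(report, "run_report"))
  man_path <- file.path(dir, "manifest.tsv")
  write_tsv(report$manifest, man_path)
  summary_path <- file.path(dir, "run_summary.txt")
  lines <- c("gbspopgen run summary", "",
             "record counts:",
             sprintf("  %s: %s", names(report$counts), report$counts),
             "", "stage timings (s):",
             sprintf("  %s: %.3f", names(report$timings),
                     report$timings),
             "", "parameters:",
             sprintf("  %s: %s", names(report$params),
                     vapply(report$params, function(x)
                       paste(format(x), collapse = ","), "")))
  writeLines(lines, summary_path)
  invisible(man_path)
}
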