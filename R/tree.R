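ibs_distance <- function(dosage) {
  obs <- (!is.na(dosage)) + 0
  A <- list((dosage == 0L) + 0, (dosage == 1L) + 0, (dosage == 2L) + 0)
  for (i in 1:3) A[[i]][is.na(A[[i]])] <- 0
  shared <- tcrossprod(obs)
  if (any(shared[upper.tri(shared)] == 0))
    stop("sample pair sharing zero observed loci; distance undefined")
  sdiff <- tcrossprod(A[[1]], A[[2]]) + tcrossprod(A[[2]], A[[1]]) +
    tcrossprod(A[[2]], A[[3]]) + tcrossprod(A[[3]], A[[2]]) +
    2 * (tcrossprod(A[[1]], A[[3]]) + tcrossprod(A[[3]], A[[1]]))
  d <- sdiff / (2 * shared)
  dimnames(d) <- list(rownames(dosage), rownames(dosage))
  d
}

#' Distance-based sample tree
#'
#' Builds a tree from identity-by-state distances (1 minus the IBS
#' allele-sharing proportion over the loci observed in both samples) by
#' UPGMA (average-linkage agglomeration) or neighbour joining, with
#' optional locus-resampling bootstrap support on internal edges.
#'
#' @param gm a [geno_matrix()] (3 or more samples).
#' @param method `"upgma"` or `"nj"`.
#' @param bootstrap_reps number of locus-resampling bootstrap replicates
#'   (0 disables support values).
#' @param seed seed for the bootstrap resampling.
#' @return A list of class `panel_tree`: `tree` (an [ape::phylo]),
#'   `dist` (the distance matrix), and `support` (per internal node, %
#'   of replicates containing the clade; `NULL` without bootstrap).
#'   Export with [ape::write.tree()].
#' @export
build_tree <- function(gm, method = c("upgma", "nj"), bootstrap_reps = 0L,
                       seed = 1L) {
  method <- match.arg(method)
  d <- gm$dosage
  if (nrow(d) < 3) stop("need at least three samples")
  D <- ibs_distance(d)
  build <- function(mat) {
    if (method == "nj") ape::nj(stats::as.dist(mat))
    else ape::as.phylo(stats::hclust(stats::as.dist(mat),
                                     method = "average"))
  }
  tree <- build(D)
  support <- NULL
  if (bootstrap_reps > 0) {
    set.seed(seed)
    boots <- vector("list", bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      loci <- sample.int(ncol(d), ncol(d), replace = TRUE)
      boots[[b]] <- build(ibs_distance(d[, loci, drop = FALSE]))
    }
    counts <- ape::prop.clades(tree, boots, rooted = method == "upgma")
    support <- 100 * counts / bootstrap_reps
  }
  structure(list(tree = tree, dist = D, support = support,
                 method = method), class = "panel_tree")
}
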