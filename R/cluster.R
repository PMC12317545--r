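#' Z-score standardized trait matrix
#'
#' Builds the genotype x (trait, treatment) matrix of genotype means for the
#' selected traits/treatments and z-standardizes each column:
#' `z = (x - mean) / sd` with the sample SD. Missing cells are imputed by
#' the column mean *before* scaling (count recorded; heatmap-style
#' clustering needs a complete matrix); constant columns are set to all
#' zeros with a warning. Column names are `<trait>_<treatment>`.
#'
#' @param means genotype-mean table from [genotypeMeans()].
#' @param traits trait codes to include (default the tolerance set
#'   SDW, RDW, TotalDW, Pupt).
#' @param treatments treatments to include (default both HP and LP).
#' @return numeric matrix (genotypes x columns) with attributes
#'   `col_mean`, `col_sd`, `n_imputed`, `constant_cols`.
#' @export
standardizeTraits <- function(means, traits = TOLERANCE_TRAITS,
                              treatments = TREATMENTS) {
  s <- means[means$trait %in% traits & means$treatment %in% treatments, ,
             drop = FALSE]
  if (!nrow(s)) .stopf("no matching (trait, treatment) means to standardize")
  ids <- sort(unique(s$genotype_id))
  cols <- as.vector(outer(traits, treatments, paste, sep = "_"))
  x <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (tr in traits) {
    for (tm in treatments) {
      sub <- s[s$trait == tr & s$treatment == tm, ]
      x[match(sub$genotype_id, ids), paste(tr, tm, sep = "_")] <- sub$mean
    }
  }
  present <- colSums(!is.na(x)) > 0
  if (!all(present)) {
    .warnf("dropping empty column(s): %s",
           paste(colnames(x)[!present], collapse = ", "))
    x <- x[, present, drop = FALSE]
  }
  n_imputed <- sum(is.na(x))
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  constant <- sdv == 0
  if (any(constant)) {
    .warnf("constant column(s) set to zero: %s",
           paste(colnames(x)[constant], collapse = ", "))
  }
  z <- sweep(x, 2, mu)
  z[, !constant] <- sweep(z[, !constant, drop = FALSE], 2,
                          sdv[!constant], "/")
  z[, constant] <- 0
  attr(z, "col_mean") <- mu
  attr(z, "col_sd") <- sdv
  attr(z, "n_imputed") <- n_imputed
  attr(z, "constant_cols") <- colnames(x)[constant]
  z
}

#' Hierarchical clustering of genotype performance profiles
#'
#' Agglomerative clustering of the standardized trait matrix on pairwise
#' Euclidean distances (default complete linkage). The dendrogram is cut at
#' `k_main` (main clusters, labelled `A`, `B`, ...) and `k_sub`
#' (sub-clusters, labelled `1..k_sub`); labels are renumbered by dendrogram
#' leaf order so the output is deterministic for a given input order.
#'
#' @param z standardized matrix from [standardizeTraits()].
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @param k_main number of main clusters (default 2).
#' @param k_sub number of sub-clusters (default 9).
#' @return list with `assignments` (data.frame `genotype_id`,
#'   `main_cluster`, `sub_cluster`) and the `hclust` object (`tree`).
#' @export
clusterGenotypes <- function(z, linkage = c("complete", "average", "ward.D2"),
                             k_main = 2, k_sub = 9) {
  linkage <- match.arg(linkage)
  if (k_sub > nrow(z)) .stopf("k_sub = %d exceeds the %d genotypes",
                              k_sub, nrow(z))
  if (k_main > k_sub) .stopf("k_main must not exceed k_sub")
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  relabel <- function(cut) {
    # renumber clusters 1..k by order of first appearance along the leaves
    first_seen <- unique(cut[hc$order])
    match(cut, first_seen)
  }
  main <- relabel(stats::cutree(hc, k = k_main))
  sub <- relabel(stats::cutree(hc, k = k_sub))
  list(assignments = data.frame(genotype_id = rownames(z),
                                main_cluster = LETTERS[main],
                                sub_cluster = sub,
                                stringsAsFactors = FALSE),
       tree = hc)
}

#' Sub-cluster mean profiles and performance classes
#'
#' Per sub-cluster mean of every (trait, treatment) genotype mean, plus a
#' reproducible best/intermediate/worst label: clusters are ranked by their
#' average rank across all columns (higher values rank higher) and split
#' into terciles — top tercile `"best"`, bottom `"worst"`, middle (and the
#' degenerate single-cluster case) `"intermediate"`.
#'
#' @param assignment assignment table from [clusterGenotypes()].
#' @param means genotype-mean table from [genotypeMeans()].
#' @param traits,treatments columns to summarize (defaults as in
#'   [standardizeTraits()]).
#' @return list with `cluster_means` (data.frame, one row per sub-cluster
#'   with `n_genotypes`, one column per `<trait>_<treatment>` and
#'   `performance_class`).
#' @export
clusterMeans <- function(assignment, means, traits = TOLERANCE_TRAITS,
                         treatments = TREATMENTS) {
  if (is.list(assignment) && !is.data.frame(assignment)) {
    assignment <- assignment$assignments
  }
  s <- means[means$trait %in% traits & means$treatment %in% treatments, ,
             drop = FALSE]
  s <- merge(s, assignment[c("genotype_id", "sub_cluster")],
             by = "genotype_id")
  if (!nrow(s)) .stopf("assignments do not cover the genotype-mean table")
  cl <- sort(unique(s$sub_cluster))
  cols <- as.vector(outer(traits, treatments, paste, sep = "_"))
  cm <- matrix(NA_real_, nrow = length(cl), ncol = length(cols),
               dimnames = list(cl, cols))
  for (tr in traits) {
    for (tm in treatments) {
      sub <- s[s$trait == tr & s$treatment == tm, ]
      if (!nrow(sub)) next
      v <- tapply(sub$mean, sub$sub_cluster, mean)
      cm[match(names(v), rownames(cm)), paste(tr, tm, sep = "_")] <- v
    }
  }
  keep_col <- colSums(!is.na(cm)) > 0
  cm <- cm[, keep_col, drop = FALSE]
  # average rank across columns; (rank - 0.5)/k puts cluster into a tercile
  rk <- apply(cm, 2, rank)
  if (is.null(dim(rk))) rk <- matrix(rk, nrow = nrow(cm))
  avg_rank <- rowMeans(rk)
  frac <- (rank(avg_rank, ties.method = "average") - 0.5) / length(cl)
  class <- ifelse(frac < 1 / 3, "worst",
                  ifelse(frac > 2 / 3, "best", "intermediate"))
  n_g <- as.integer(table(factor(assignment$sub_cluster, levels = cl)))
  out <- data.frame(sub_cluster = cl, n_genotypes = n_g,
                    as.data.frame(cm, check.names = FALSE),
                    performance_class = class, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(cluster_means = out)
}
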