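# Clustering of occupancy-change profiles and cluster-wise statistics:
# replicate (pair) selection, Ward hierarchical clustering of per-gene
# fold-change features, canonical I/II/III labelling by polymerase gene-body
# depletion, matched-pair median-of-ratios summaries, per-cluster Spearman
# correlations, fraction-decreased summaries, and the WT-vs-null Wilcoxon
# comparison of cluster expression.

#' Select the most-affected matched pairs
#'
#' Scores each matched animal pair by the mean absolute log2 fold change
#' over all genes and bins, summed across the modalities present, and keeps
#' the top `n_select`. Ties are broken by lexicographic pair id.
#'
#' @param fc_matrices list of `fold_change_matrix` objects (any mix of
#'   pairs and modalities; each carries its `pair_id`).
#' @param n_select number of pairs to keep.
#' @return Character vector of selected pair ids (sorted).
#' @export
select_pairs <- function(fc_matrices, n_select = 2) {
  pair_ids <- vapply(fc_matrices, `[[`, "", "pair_id")
  scores_each <- vapply(fc_matrices, function(m) mean(abs(m$values)), 0)
  score <- vapply(split(scores_each, pair_ids), sum, 0)
  if (n_select > length(score))
    .stopf("n_select (%d) exceeds available pairs (%d)", n_select, length(score))
  o <- order(-score, names(score))
  sort(names(score)[o][seq_len(n_select)])
}

#' Hierarchical clustering of gene features
#'
#' Agglomerative clustering (default Ward linkage on Euclidean distance) of
#' a gene x feature table, cut at `k` clusters. Each feature column is
#' standardized to zero mean, unit variance first (constant columns are
#' left centred). Deterministic given the input.
#'
#' @param features numeric matrix or data.frame, genes in rows (row names =
#'   gene ids), finite values.
#' @param k number of clusters.
#' @param linkage linkage method for [stats::hclust()] (`"ward.D2"`
#'   default).
#' @param distance distance metric for [stats::dist()].
#' @param standardize standardize columns first?
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named integer cluster per gene, 1..k), `features`, `k`, `linkage`,
#'   `distance`.
#' @export
cluster_genes <- function(features, k = 3, linkage = "ward.D2",
                          distance = "euclidean", standardize = TRUE) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) .stopf("features must have gene row names")
  if (!all(is.finite(features))) {
    bad <- rownames(features)[!apply(is.finite(features), 1, all)]
    .stopf("non-finite feature value(s) for gene(s): %s",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (k > nrow(features)) .stopf("k (%d) exceeds number of genes (%d)", k, nrow(features))
  x <- features
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    x <- scale(x, center = TRUE, scale = ifelse(s > 0, s, 1))
  }
  hc <- stats::hclust(stats::dist(x, method = distance), method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, features = features, k = k,
                 linkage = linkage, distance = distance),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("cluster_assignment: %d genes in %d clusters (%s)\n",
              length(x$labels), x$k,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Canonical I/II/III cluster labels
#'
#' Orders the three clusters by mean polymerase gene-body log2 fold change:
#' the least negative becomes cluster I, the most negative cluster III, the
#' remaining one cluster II. A tie in the ordering statistic is an error
#' (never silently arbitrary).
#'
#' @param assignment a `cluster_assignment` with `k = 3`.
#' @param pol2_body_fc named numeric vector: per-gene polII gene-body log2
#'   fold change (names = gene ids).
#' @return The assignment with a `canonical` component (named character
#'   vector of "I"/"II"/"III" per gene) and `cluster_means`.
#' @export
label_clusters <- function(assignment, pol2_body_fc) {
  if (assignment$k != 3) .stopf("canonical labelling requires k = 3")
  fc <- pol2_body_fc[names(assignment$labels)]
  if (anyNA(fc)) .stopf("pol2_body_fc missing for some genes")
  means <- tapply(fc, assignment$labels, mean)
  if (anyDuplicated(means))
    .stopf("tie in mean polII body fold change between clusters; supply labels manually")
  o <- order(means, decreasing = TRUE)          # least negative first
  map <- stats::setNames(c("I", "II", "III"), names(means)[o])
  assignment$canonical <- stats::setNames(
    unname(map[as.character(assignment$labels)]), names(assignment$labels))
  assignment$cluster_means <- stats::setNames(as.numeric(means), names(means))
  assignment
}

#' Matched-pair median-of-ratios per gene
#'
#' For each gene, forms `(null_i + delta) / (WT_i + delta)` on a chosen
#' region summary for every matched pair i, then takes the median across
#' pairs (mean of the middle two for even counts). This keeps
#' replicate-level information: a gene must move consistently across
#' matched animal pairs to show a shifted median ratio.
#'
#' @param summaries_null,summaries_wt named lists (by pair id) of region
#'   summary data.frames from [summarize_regions()]; the two lists must
#'   cover the same pairs and genes.
#' @param region `"tss"`, `"body"`, `"tes"`, `"upstream"` or
#'   `"downstream"`.
#' @param delta pseudocount.
#' @param pairs optional subset of pair ids to use.
#' @return data.frame: `gene_id`, one `ratio_<pair>` column per pair,
#'   `median_ratio`.
#' @export
median_ratio_per_gene <- function(summaries_null, summaries_wt,
                                  region = c("body", "tss", "tes", "upstream", "downstream"),
                                  delta = 1.0, pairs = NULL) {
  region <- match.arg(region)
  .check_scalar_num(delta, "delta", positive = TRUE)
  if (is.null(pairs)) pairs <- names(summaries_null)
  miss <- setdiff(pairs, intersect(names(summaries_null), names(summaries_wt)))
  if (length(miss)) .stopf("missing pair(s): %s", paste(miss, collapse = ", "))
  ids <- summaries_null[[pairs[1]]]$gene_id
  ratios <- sapply(pairs, function(p) {
    sn <- summaries_null[[p]]; sw <- summaries_wt[[p]]
    if (!identical(sn$gene_id, ids) || !identical(sw$gene_id, ids))
      .stopf("gene sets differ across pairs")
    (sn[[region]] + delta) / (sw[[region]] + delta)
  })
  ratios <- matrix(ratios, nrow = length(ids),
                   dimnames = list(NULL, paste0("ratio_", pairs)))
  out <- data.frame(gene_id = ids, ratios,
                    median_ratio = apply(ratios, 1, stats::median),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}

# Spearman rho with average-rank ties; two-sided P by exact permutation
# enumeration for n <= 8, t-approximation otherwise.
.spearman_test <- function(x, y, exact_n = 8) {
  n <- length(x)
  if (n < 3) .stopf("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.na(rho)) .stopf("constant input: Spearman correlation undefined")
  if (n <= exact_n) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    if (!is.finite(t)) p <- 0
  }
  list(rho = rho, p = min(p, 1), n = n)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Per-cluster Spearman correlation
#'
#' Correlates two per-gene quantities (e.g. median AFF4 body ratio vs
#' median polII body ratio, or vs RNA expression ratio) within each
#' cluster.
#'
#' @param x,y named numeric vectors (names = gene ids) covering all
#'   clustered genes.
#' @param clusters named character/integer vector: gene -> cluster label.
#' @param x_name,y_name reported modality names.
#' @return data.frame: `cluster`, `x`, `y`, `rho`, `p`, `n`.
#' @export
spearman_by_cluster <- function(x, y, clusters, x_name = "x", y_name = "y") {
  out <- lapply(sort(unique(as.character(clusters))), function(cl) {
    ids <- names(clusters)[clusters == cl]
    if (length(ids) < 3) .stopf("cluster %s has fewer than 3 genes", cl)
    xi <- x[ids]; yi <- y[ids]
    if (anyNA(xi) || anyNA(yi))
      .stopf("missing values for cluster %s", cl)
    st <- .spearman_test(xi, yi)
    data.frame(cluster = cl, x = x_name, y = y_name,
               rho = st$rho, p = st$p, n = st$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of genes with decreased occupancy
#'
#' Fraction of genes whose matched-pair median null/WT ratio is strictly
#' below 1.
#'
#' @param median_ratios numeric vector of per-gene median ratios (or a
#'   data.frame from [median_ratio_per_gene()]).
#' @return A fraction in `[0, 1]`.
#' @export
fraction_decreased <- function(median_ratios) {
  if (is.data.frame(median_ratios)) median_ratios <- median_ratios$median_ratio
  if (!length(median_ratios)) .stopf("empty input")
  mean(median_ratios < 1)
}

#' Wilcoxon rank-sum comparison of cluster expression
#'
#' For each cluster, compares per-gene mean RPM between genotypes with a
#' two-sided Wilcoxon rank-sum test (exact when both groups have <= 8
#' observations, normal approximation with continuity correction
#' otherwise). An all-tied degenerate input yields P = 1 with a warning.
#'
#' @param expr an `expression_table`.
#' @param clusters named vector: gene -> cluster label (genes must exist in
#'   `expr`).
#' @param delta pseudocount for the reported median expression ratio.
#' @return data.frame: `cluster`, `n_genes`, `statistic`, `p`,
#'   `median_ratio` (median per-gene (null+delta)/(WT+delta)), `direction`.
#' @export
compare_cluster_expression <- function(expr, clusters, delta = 1.0) {
  mr <- genotype_mean_rpm(expr)
  idx <- match(names(clusters), mr$gene_id)
  if (anyNA(idx)) .stopf("clustered gene(s) missing from expression table")
  out <- lapply(sort(unique(as.character(clusters))), function(cl) {
    sel <- idx[clusters == cl]
    if (length(sel) < 3) .stopf("cluster %s has fewer than 3 genes", cl)
    wt <- mr$WT[sel]; nl <- mr$null[sel]
    if (length(unique(c(wt, nl))) == 1L) {
      .warnf("cluster %s: all expression values tied; P = 1", cl)
      w <- length(wt) * length(nl) / 2
      p <- 1
    } else {
      use_exact <- length(wt) <= 8 && length(nl) <= 8
      ht <- suppressWarnings(stats::wilcox.test(nl, wt, exact = use_exact,
                                                correct = TRUE))
      w <- unname(ht$statistic)
      p <- ht$p.value
      if (w == length(wt) * length(nl) / 2) p <- 1
    }
    ratio <- stats::median((nl + delta) / (wt + delta))
    data.frame(cluster = cl, n_genes = length(sel), statistic = w, p = p,
               median_ratio = ratio,
               direction = if (ratio < 1) "down" else if (ratio > 1) "up" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
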