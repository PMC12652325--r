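fake_fc <- function(pair_id, value, n = 4, bins = 6) {
  structure(list(values = matrix(value, n, bins,
                                 dimnames = list(sprintf("g%d", 1:n), NULL)),
                 pair_id = pair_id, modality = "polII",
                 layout = region_layout(), delta = 1),
            class = "fold_change_matrix")
}

test_that("pair selection ranks by mean absolute fold change with stable ties", {
  fcs <- list(fake_fc("p1", 0.10), fake_fc("p2", -0.50), fake_fc("p3", 0.60))
  expect_equal(select_pairs(fcs, 2), c("p2", "p3"))
  ties <- list(fake_fc("p1", 0.3), fake_fc("p2", 0.3), fake_fc("p3", 0.3))
  expect_equal(select_pairs(ties, 2), c("p1", "p2"))
  zero <- list(fake_fc("p1", 0), fake_fc("p2", 1e-6))
  expect_equal(select_pairs(zero, 1), "p2")
  expect_error(select_pairs(fcs, 4), "exceeds")
  # modalities sum per pair
  both <- list(fake_fc("p1", 0.2), fake_fc("p2", 0.3),
               fake_fc("p1", 0.5), fake_fc("p2", 0.1))
  expect_equal(select_pairs(both, 1), "p1")
})

test_that("well-separated point masses are recovered exactly and deterministically", {
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  x <- centers[rep(1:3, each = 20), ] + 0
  rownames(x) <- sprintf("g%03d", 1:60)
  a1 <- cluster_genes(x, k = 3)
  a2 <- cluster_genes(x, k = 3)
  expect_identical(a1$labels, a2$labels)
  expect_equal(length(unique(a1$labels[1:20])), 1L)
  expect_equal(length(unique(a1$labels)), 3L)
  expect_equal(adjusted_rand_index(a1$labels, rep(1:3, each = 20)), 1)
  one <- cluster_genes(x, k = 1)
  expect_equal(unname(unique(one$labels)), 1L)
  expect_error(cluster_genes(x, k = 100), "exceeds")
  x[3, 1] <- NA
  expect_error(cluster_genes(x, k = 3), "g003")
})

test_that("canonical labels follow mean polII body depletion, ties error", {
  labels <- stats::setNames(rep(1:3, each = 5), sprintf("g%d", 1:15))
  asg <- structure(list(labels = labels, k = 3), class = "cluster_assignment")
  fc <- stats::setNames(rep(c(-0.05, -0.4, -1.2), each = 5), names(labels))
  out <- label_clusters(asg, fc)
  expect_equal(unname(out$canonical[c(1, 6, 11)]), c("I", "II", "III"))
  fc_tie <- stats::setNames(rep(c(-0.4, -0.4, -1.2), each = 5), names(labels))
  expect_error(label_clusters(asg, fc_tie), "tie")
})

test_that("median of ratios is the standard order statistic and pair-order invariant", {
  mk_sums <- function(vals) lapply(vals, function(v)
    data.frame(gene_id = "g1", tss = 0, body = v, tes = 0,
               upstream = 0, downstream = 0))
  delta <- 1e-9
  ratios_of <- function(null_vals) {
    nm <- paste0("p", seq_along(null_vals))
    wt_vals <- rep(1, length(null_vals))
    median_ratio_per_gene(stats::setNames(mk_sums(null_vals), nm),
                          stats::setNames(mk_sums(wt_vals), nm),
                          region = "body", delta = delta)$median_ratio
  }
  expect_equal(ratios_of(c(0.5, 1, 2)), 1.0, tolerance = 1e-6)
  expect_equal(ratios_of(c(0.2, 0.4, 0.8)), 0.4, tolerance = 1e-6)
  expect_equal(ratios_of(c(0.2, 0.4, 0.6, 0.8)), 0.5, tolerance = 1e-6)
  # permuting the pairs leaves the median unchanged
  expect_equal(ratios_of(c(0.8, 0.2, 0.6, 0.4)), 0.5, tolerance = 1e-6)
  expect_error(median_ratio_per_gene(stats::setNames(mk_sums(list(1)), "p1"),
                                     stats::setNames(mk_sums(list(1)), "p2")),
               "missing pair")
})

test_that("Spearman rho and p behave on monotone, hand-worked and asymptotic cases", {
  st <- occudiff:::.spearman_test
  expect_equal(st(1:10, (1:10)^3)$rho, 1)
  expect_equal(st(1:10, -(1:10))$rho, -1)
  # 5-point worked example: d^2 = (1,1,1,1,0), rho = 1 - 6*4/(5*24) = 0.8
  ex <- st(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(ex$rho, 0.8)
  expect_equal(ex$rho, stats::cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                                  method = "spearman"))
  # exact permutation p for a perfect 5-point monotone pattern: only the
  # identity and the reversal of 120 orderings reach |rho| = 1
  expect_equal(st(1:5, 1:5)$p, 2 / 120)
  # large-n t-approximation agrees with cor.test's asymptotic p
  set.seed(8)
  x <- stats::rnorm(60); y <- x + stats::rnorm(60, sd = 2)
  ours <- st(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("per-cluster correlation handles ties and small clusters", {
  cl <- stats::setNames(rep(c("I", "II"), each = 30), sprintf("g%d", 1:60))
  set.seed(12)
  x <- stats::setNames(stats::rnorm(60), names(cl))
  y <- x + stats::rnorm(60)
  res <- spearman_by_cluster(x, y, cl)
  expect_equal(res$cluster, c("I", "II"))
  expect_equal(res$n, c(30L, 30L))
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  tiny <- stats::setNames(rep("I", 2), c("g1", "g2"))
  expect_error(spearman_by_cluster(x[1:2], y[1:2], tiny), "fewer than 3")
})

test_that("fraction decreased uses a strict below-one rule", {
  expect_equal(fraction_decreased(rep(0.5, 10)), 1.0)
  expect_equal(fraction_decreased(rep(1.0, 10)), 0.0)
  expect_equal(fraction_decreased(c(0.5, 1.0, 2.0, 0.9)), 0.5)
  expect_equal(fraction_decreased(data.frame(median_ratio = c(0.3, 1.5))), 0.5)
})

test_that("Wilcoxon comparison matches exact enumeration and degenerate rules", {
  mk_expr <- function(wt, null, total = 1000L) {
    # a filler gene equalizes library sizes so the RPM of the genes of
    # interest stays proportional to the stated counts
    wt <- c(wt, total - sum(wt)); null <- c(null, total - sum(null))
    counts <- cbind(matrix(rep(wt, 2), ncol = 2), matrix(rep(null, 2), ncol = 2))
    storage.mode(counts) <- "integer"
    rownames(counts) <- c(sprintf("g%d", seq_along(wt)[-length(wt)]), "filler")
    colnames(counts) <- c("w1", "w2", "n1", "n2")
    expression_table(counts, c("WT", "WT", "null", "null"))
  }
  # complete separation at 3 vs 3 genes: exact two-sided p = 0.1
  cl <- stats::setNames(rep("I", 3), c("g1", "g2", "g3"))
  expr <- mk_expr(c(1L, 2L, 3L), c(10L, 20L, 30L))
  res <- compare_cluster_expression(expr, cl)
  mr <- genotype_mean_rpm(expr)
  mr <- mr[mr$gene_id %in% names(cl), ]
  orc <- oracle_wilcoxon(mr$null, mr$WT)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, orc$p)
  expect_equal(res$statistic, orc$statistic)
  expect_equal(res$direction, "up")
  # identical WT and null means: p = 1
  same <- mk_expr(c(5L, 9L, 13L), c(5L, 9L, 13L))
  expect_equal(compare_cluster_expression(same, cl)$p, 1)
  # all-tied degenerate input warns and returns p = 1
  flat <- mk_expr(c(7L, 7L, 7L), c(7L, 7L, 7L))
  expect_warning(res_flat <- compare_cluster_expression(flat, cl), "tied")
  expect_equal(res_flat$p, 1)
})

test_that("adjusted Rand index agrees with mclust and known anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  set.seed(14)
  for (i in 1:20) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
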