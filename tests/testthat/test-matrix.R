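toy_ann <- function(start, end, strand = "+", L = 50000) {
  genome_annotation(data.frame(gene_id = "g1", chrom = "chr1",
                               start = start, end = end, strand = strand),
                    c(chr1 = L))
}

test_that("uniform coverage fills every matrix cell and summary with the same value", {
  ann <- toy_ann(10000, 16000)
  tr <- uniform_track(3.5, 50000)
  m <- build_scaled_matrix(tr, ann, "g1")
  expect_true(all(abs(m$values - 3.5) < 1e-12))
  s <- summarize_regions(tr, ann, "g1")
  expect_equal(unlist(s[, -1], use.names = FALSE), rep(3.5, 5))
})

test_that("body-only coverage with log2 transform gives log2(c+1) body, zero flanks", {
  ann <- toy_ann(10000, 16000)
  tr <- coverage_track(data.frame(chrom = "chr1", start = 10000, end = 16000,
                                  value = 4.0), c(chr1 = 50000))
  m <- build_scaled_matrix(tr, ann, "g1", log2_transform = TRUE)
  n_up <- 40
  expect_equal(unname(m$values[1, n_up + 50]), log2(5))
  expect_equal(unname(m$values[1, 1]), 0)
  expect_equal(unname(m$values[1, ncol(m$values)]), 0)
})

test_that("body bins follow 5'->3' orientation on both strands", {
  lay <- region_layout(body_bins = 3)
  tr <- coverage_track(data.frame(chrom = "chr1",
                                  start = c(10000, 11000, 12000),
                                  end = c(11000, 12000, 13000),
                                  value = c(1, 2, 3)), c(chr1 = 50000))
  m_plus <- build_scaled_matrix(tr, toy_ann(10000, 13000, "+"), "g1", lay)
  m_minus <- build_scaled_matrix(tr, toy_ann(10000, 13000, "-"), "g1", lay)
  body_cols <- 40 + 1:3
  expect_equal(unname(m_plus$values[1, body_cols]), c(1, 2, 3))
  expect_equal(unname(m_minus$values[1, body_cols]), c(3, 2, 1))
})

test_that("matrix and summaries agree with the per-base oracle on random genes", {
  set.seed(31)
  lay <- region_layout(body_bins = 20)
  for (i in 1:50) {
    L <- 30000
    start <- sample(3000:10000, 1)
    len <- sample(2000:10000, 1)
    strand <- sample(c("+", "-"), 1)
    ann <- toy_ann(start, start + len, strand, L)
    n <- 40
    s0 <- sort(sample.int(L - 100, n))
    runs <- data.frame(chrom = "chr1", start = s0,
                       end = pmin(s0 + sample.int(600, n), L),
                       value = round(stats::rexp(n) * 4, 4))
    runs <- occudiff:::.runs_from_intervals(runs$chrom, runs$start, runs$end,
                                            runs$value)
    tr <- coverage_track(runs, c(chr1 = L))
    pb <- oracle_perbase(runs, "chr1", L)

    m <- build_scaled_matrix(tr, ann, "g1", lay)
    expect_equal(unname(m$values[1, ]),
                 oracle_matrix_row(pb, start, start + len, strand, lay),
                 tolerance = 1e-9)

    s <- summarize_regions(tr, ann, "g1", lay)
    t0 <- if (strand == "+") start else start + len
    t1 <- if (strand == "+") start + len else start
    expect_equal(s$tss, oracle_window_mean(pb, t0 - 250, t0 + 250), tolerance = 1e-9)
    expect_equal(s$tes, oracle_window_mean(pb, t1 - 250, t1 + 250), tolerance = 1e-9)
    expect_equal(s$body, oracle_window_mean(pb, start + 250, start + len - 250),
                 tolerance = 1e-9)
  }
})

test_that("coordinate reflection with strand flip leaves the matrix unchanged", {
  set.seed(37)
  L <- 30000
  lay <- region_layout(body_bins = 15)
  for (i in 1:10) {
    start <- sample(4000:8000, 1); len <- sample(2500:9000, 1)
    strand <- sample(c("+", "-"), 1)
    n <- 25
    s0 <- sort(sample.int(L - 200, n))
    runs <- occudiff:::.runs_from_intervals(
      rep("chr1", n), s0, s0 + sample.int(300, n), round(stats::rexp(n), 3))
    tr <- coverage_track(runs, c(chr1 = L))
    m1 <- build_scaled_matrix(tr, toy_ann(start, start + len, strand, L), "g1", lay)
    refl_runs <- data.frame(chrom = "chr1", start = L - runs$end,
                            end = L - runs$start, value = runs$value)
    tr2 <- coverage_track(refl_runs, c(chr1 = L))
    m2 <- build_scaled_matrix(
      tr2, toy_ann(L - (start + len), L - start,
                   if (strand == "+") "-" else "+", L), "g1", lay)
    expect_equal(m2$values, m1$values, tolerance = 1e-9)
  }
})

test_that("body bin means conserve total body coverage area", {
  set.seed(41)
  L <- 30000
  lay <- region_layout(body_bins = 33)
  start <- 9000; len <- 7321   # deliberately not divisible by 33
  n <- 30
  s0 <- sort(sample.int(L - 200, n))
  runs <- occudiff:::.runs_from_intervals(
    rep("chr1", n), s0, s0 + sample.int(400, n), round(stats::rexp(n), 3))
  tr <- coverage_track(runs, c(chr1 = L))
  m <- build_scaled_matrix(tr, toy_ann(start, start + len), "g1", lay)
  body <- m$values[1, 40 + seq_len(33)]
  area <- sum(body) * len / 33
  pb <- oracle_perbase(runs, "chr1", L)
  expect_equal(area, sum(pb[(start + 1):(start + len)]), tolerance = 1e-9)
})

test_that("log2 fold-change matrices obey identity, antisymmetry and hand arithmetic", {
  ann <- toy_ann(10000, 16000)
  mk <- function(v) build_scaled_matrix(uniform_track(v, 50000), ann, "g1")
  fc0 <- pairwise_log2fc(mk(2), mk(2), delta = 1)
  expect_true(all(fc0$values == 0))
  fc <- pairwise_log2fc(mk(2), mk(1), delta = 1)
  expect_true(all(abs(fc$values - log2(3 / 2)) < 1e-12))
  fc_swap <- pairwise_log2fc(mk(1), mk(2), delta = 1)
  expect_equal(fc_swap$values, -fc$values)
  small <- pairwise_log2fc(mk(2), mk(1), delta = 1e-9)
  expect_true(all(abs(small$values - 1) < 1e-6))
  m_log <- build_scaled_matrix(uniform_track(2, 50000), ann, "g1",
                               log2_transform = TRUE)
  expect_error(pairwise_log2fc(m_log, mk(1)), "linear scale")
})

test_that("metagene profiles are row means with cluster restriction", {
  g <- data.frame(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                  start = seq(5000, 95000, by = 10000),
                  end = seq(5000, 95000, by = 10000) + 4000, strand = "+")
  ann <- genome_annotation(g, c(chr1 = 2e5))
  tr <- uniform_track(1, 2e5)
  m <- build_scaled_matrix(tr, ann, g$gene_id)
  set.seed(4)
  m$values <- matrix(stats::rnorm(length(m$values)), nrow = 10,
                     dimnames = dimnames(m$values))
  one <- metagene_profile(m, "g3")
  expect_equal(one$profile, m$values["g3", ])
  expect_equal(one$n_genes, 1L)
  m2 <- m; m2$values[2, ] <- -m2$values[1, ]
  expect_equal(unname(metagene_profile(m2, c("g1", "g2"))$profile),
               rep(0, ncol(m2$values)))
  sel <- c("g2", "g5", "g9")
  expect_equal(metagene_profile(m, sel)$profile, colMeans(m$values[sel, ]))
  expect_error(metagene_profile(m, character(0)), "empty")
})

test_that("TSS/TES window collisions on too-short genes are reported", {
  ann <- toy_ann(10000, 10400)   # 400 bp gene cannot host 250 bp windows
  expect_error(summarize_regions(uniform_track(1, 50000), ann, "g1"),
               "g1")
})
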