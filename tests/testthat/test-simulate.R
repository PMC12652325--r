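test_that("generation is a pure function of design and seed", {
  d <- simulation_design(n_genes = 60, seed = 9)
  a1 <- generate_annotation(d)
  a2 <- generate_annotation(d)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))
  s1 <- simulate_chip_experiment(a1$annotation, a1$truth, d)
  s2 <- simulate_chip_experiment(a2$annotation, a2$truth, d)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  r1 <- simulate_rnaseq_counts(a1$annotation, a1$truth, d)
  r2 <- simulate_rnaseq_counts(a2$annotation, a2$truth, d)
  expect_identical(r1$expr$counts, r2$expr$counts)
  d2 <- simulation_design(n_genes = 60, seed = 10)
  expect_false(identical(generate_annotation(d2)$annotation$genes$start,
                         a1$annotation$genes$start))
})

test_that("planted filter violations are exact counts, not samples", {
  d <- simulation_design(n_genes = 1000, frac_short = 0.2, frac_close = 0.1,
                         frac_unoccupied = 0.05, seed = 3)
  ga <- generate_annotation(d)
  lens <- gene_lengths(ga$annotation)
  expect_equal(sum(lens < 2000), 200L)
  expect_equal(sum(ga$truth$type == "close"), 100L)
  expect_equal(sum(ga$truth$type == "unoccupied"), 50L)
  # with no planted violations, every gene passes length and gap filters
  d0 <- simulation_design(n_genes = 100, frac_short = 0, frac_close = 0,
                          frac_unoccupied = 0, seed = 3)
  ga0 <- generate_annotation(d0)
  u <- filter_gene_universe(ga0$annotation, ga0$truth$gene_id)
  expect_equal(u$n, 100L)
  expect_error(generate_annotation(simulation_design(n_genes = 100, seed = 1,
                                                     chrom_length = 1e4)),
               "too small")
})

test_that("all-unit effects give matched WT/null coverage on average", {
  eff <- occudiff:::.default_effects()
  for (cl in names(eff)) for (m in names(eff[[cl]]))
    eff[[cl]][[m]][] <- 1
  d <- simulation_design(n_genes = 150, effects = eff, effect_jitter_sd = 0,
                         aff4_flank_sd = 0, effect_sd_c3 = 0,
                         spikein_noise = FALSE, seed = 13)
  sim <- simulate_dataset(d)
  univ <- sim$truth$gene_id[sim$truth$in_universe]
  r <- modality_median_ratios(sim$chip$tracks, sim$chip$sheet, sim$annotation,
                              univ, "polII", delta = 0.01)
  expect_lt(abs(mean(log2(r))), 0.05)
})

test_that("a planted body multiplier is recovered as its log2 on realized coverage", {
  eff <- occudiff:::.default_effects()
  for (cl in names(eff)) for (m in names(eff[[cl]])) eff[[cl]][[m]][] <- 1
  eff$III$polII["body"] <- 0.5
  d <- simulation_design(n_genes = 300,
                         cluster_props = c(I = 0.01, II = 0.01, III = 0.98),
                         effects = eff, effect_jitter_sd = 0, effect_sd_c3 = 0,
                         cluster3_weight_boost = 4, weight_sdlog = 0.1,
                         spikein_noise = FALSE, seed = 17)
  sim <- simulate_dataset(d)
  ids3 <- sim$truth$gene_id[sim$truth$label == "III"]
  # measure with a negligible pseudocount so attenuation does not bias the
  # comparison against the analytic expectation log2(0.5) = -1
  r <- modality_median_ratios(sim$chip$tracks, sim$chip$sheet, sim$annotation,
                              ids3, "polII", delta = 1e-6)
  expect_lt(abs(mean(log2(r)) - log2(0.5)), 0.1)
})

test_that("realized fragment counts match the closed-form mean within Monte Carlo error", {
  base <- simulation_design(n_genes = 30, n_pairs = 1, frac_short = 0,
                            frac_close = 0, frac_unoccupied = 0,
                            spikein_noise = FALSE, seed = 100)
  ga <- generate_annotation(base)
  n_rep <- 200
  totals <- matrix(0, n_rep, 2)   # WT / null total fragments, AFF4
  for (k in seq_len(n_rep)) {
    d <- base; d$seed <- base$seed + k
    chip <- simulate_chip_experiment(ga$annotation, ga$truth, d)
    sheet <- as.data.frame(chip$sheet)
    wt <- sheet$sample_id[sheet$modality == "AFF4" & sheet$genotype == "WT"]
    totals[k, 1] <- chip$tracks[[wt]]$target$total_fragments
  }
  # WT expectation: depth x sum of weights x multiplier (region masses sum to 1)
  mult <- rep_len(base$spikein_multipliers, 2)[1]
  expected <- base$depth * sum(ga$truth$weight) * mult
  var_one <- sum(base$depth^2 * ga$truth$weight^2 * mult^2 * base$dispersion +
                 base$depth * ga$truth$weight * mult)
  se <- sqrt(var_one / n_rep)
  expect_lt(abs(mean(totals[, 1]) - expected), 3 * se)
})

test_that("RNA counts order clusters III < II < 1 < I in null/WT ratio", {
  d <- simulation_design(n_genes = 800, seed = 21)
  ga <- generate_annotation(d)
  rna <- simulate_rnaseq_counts(ga$annotation, ga$truth, d)
  mr <- genotype_mean_rpm(rna$expr)
  ratio <- (mr$null + 1) / (mr$WT + 1)
  med <- tapply(ratio, ga$truth$label[match(mr$gene_id, ga$truth$gene_id)],
                stats::median)
  expect_lt(med[["III"]], med[["II"]])
  expect_lt(med[["II"]], 1)
  expect_gt(med[["I"]], 1)
  # cluster III carries the highest baseline expression
  wt_med <- tapply(mr$WT, ga$truth$label[match(mr$gene_id, ga$truth$gene_id)],
                   stats::median)
  expect_gt(wt_med[["III"]], max(wt_med[["I"]], wt_med[["II"]]))
  # null case: all multipliers 1
  d0 <- d; d0$rna_multipliers <- c(I = 1, II = 1, III = 1)
  d0$rna_jitter_sd <- 0; d0$effect_sd_c3 <- 0
  rna0 <- simulate_rnaseq_counts(ga$annotation, ga$truth, d0)
  mr0 <- genotype_mean_rpm(rna0$expr)
  med0 <- tapply((mr0$null + 1) / (mr0$WT + 1),
                 ga$truth$label[match(mr0$gene_id, ga$truth$gene_id)],
                 stats::median)
  expect_true(all(abs(med0[c("I", "II", "III")] - 1) < 0.1))
  d_bad <- d; d_bad$rna_dispersion <- 0
  expect_error(simulate_rnaseq_counts(ga$annotation, ga$truth, d_bad),
               "dispersion")
})
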