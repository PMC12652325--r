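test_that("peak overlap at the promoter window marks genes occupied per quorum", {
  g <- data.frame(gene_id = "gA", chrom = "chr1", start = 1000, end = 6000,
                  strand = "+")
  ann <- genome_annotation(g, c(chr1 = 20000))
  hit <- data.frame(chrom = "chr1", start = 990, end = 1010)
  far <- data.frame(chrom = "chr1", start = 15000, end = 15100)
  expect_equal(detect_occupied_genes(ann, peaks = list(hit), mode = "peaks"), "gA")
  expect_equal(detect_occupied_genes(ann, peaks = list(far), mode = "peaks"),
               character(0))
  # 2 of 3 replicates with a peak: occupied at quorum 2, not at quorum 3
  reps <- list(hit, hit, far)
  expect_equal(detect_occupied_genes(ann, peaks = reps, mode = "peaks", quorum = 2),
               "gA")
  expect_equal(detect_occupied_genes(ann, peaks = reps, mode = "peaks", quorum = 3),
               character(0))
  expect_warning(
    detect_occupied_genes(ann, peaks = list(hit, data.frame(chrom = character(),
                                                            start = numeric(),
                                                            end = numeric())),
                          mode = "peaks", quorum = 1),
    "empty peak set")
})

test_that("threshold mode requires promoter coverage above the genomic median", {
  g <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                  start = c(5000, 12000), end = c(9000, 16000), strand = "+")
  ann <- genome_annotation(g, c(chr1 = 40000))
  # background 1.0 everywhere, strong promoter signal only on gA
  tr <- coverage_track(data.frame(chrom = "chr1",
                                  start = c(0, 4000), end = c(4000, 40000),
                                  value = c(1, 1)), c(chr1 = 40000))
  tr$runs <- occudiff:::.runs_from_intervals(
    rep("chr1", 2), c(0, 4500), c(40000, 5500), c(1, 9))
  expect_equal(detect_occupied_genes(ann, tracks = list(tr), mode = "threshold"),
               "gA")
  zero <- coverage_track(data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), value = numeric()),
                         c(chr1 = 40000))
  expect_equal(detect_occupied_genes(ann, tracks = list(zero), mode = "threshold"),
               character(0))
})

test_that("length and neighbour-gap boundaries follow the strict/inclusive rules", {
  mk <- function(spans) {
    g <- data.frame(gene_id = sprintf("g%d", seq_along(spans)),
                    chrom = "chr1",
                    start = vapply(spans, `[[`, 0, 1),
                    end = vapply(spans, `[[`, 0, 2),
                    strand = "+")
    genome_annotation(g, c(chr1 = 1e6))
  }
  # gap of exactly 2000 is allowed (inclusive)
  u <- filter_gene_universe(mk(list(c(0, 3000), c(5000, 9000))), c("g1", "g2"))
  expect_equal(u$gene_ids, c("g1", "g2"))
  # length of exactly 2000 is rejected (strict "longer than")
  u <- filter_gene_universe(mk(list(c(0, 2000))), "g1")
  expect_equal(u$n, 0L)
  expect_false(u$outcomes$length_ok)
  # gap 1000: both neighbours fail even though occupied and long
  u <- filter_gene_universe(mk(list(c(0, 3000), c(4000, 8000))), c("g1", "g2"))
  expect_equal(u$gene_ids, character(0))
  expect_equal(u$outcomes$gap_ok, c(FALSE, FALSE))
  # overlap counts as gap 0
  u <- filter_gene_universe(mk(list(c(0, 3000), c(2500, 7000))), c("g1", "g2"))
  expect_equal(u$outcomes$neighbor_gap, c(0, 0))
})

test_that("sweep-based filtering matches the all-pairs oracle on random annotations", {
  set.seed(19)
  for (i in 1:200) {
    ann <- random_toy_annotation(sample(2:50, 1))
    occ <- sample(ann$genes$gene_id, sample.int(nrow(ann$genes), 1))
    got <- filter_gene_universe(ann, occ)$gene_ids
    expect_identical(got, oracle_filter(ann$genes, occ))
  }
})

test_that("shrinking the occupied set never grows the universe", {
  set.seed(23)
  for (i in 1:20) {
    ann <- random_toy_annotation(30)
    occ <- sample(ann$genes$gene_id, 25)
    full <- filter_gene_universe(ann, occ)$gene_ids
    sub <- filter_gene_universe(ann, sample(occ, 15))$gene_ids
    expect_true(all(sub %in% full))
  }
})

test_that("the generator's intended universe is recovered exactly", {
  d <- simulation_design(n_genes = 400, seed = 5)
  sim <- simulate_dataset(d)
  sheet <- as.data.frame(sim$chip$sheet)
  wt_pol2 <- sheet$sample_id[sheet$modality == "polII" & sheet$genotype == "WT"]
  st <- compute_scale_factors(
    sheet[sheet$modality == "polII", c("sample_id", "spikein_fragments")])
  tracks <- lapply(wt_pol2, function(s)
    normalize_track(sim$chip$tracks[[s]]$target,
                    st$scale_factor[st$sample_id == s]))
  occ <- detect_occupied_genes(sim$annotation, tracks = tracks, mode = "threshold")
  u <- filter_gene_universe(sim$annotation, occ)
  expect_identical(sort(u$gene_ids),
                   sort(sim$truth$gene_id[sim$truth$in_universe]))
})
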