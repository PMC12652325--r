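# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation: per-base expansion instead of
# cumulative areas, all-pairs scans instead of sorted sweeps, full
# permutation enumeration instead of closed forms.

# per-base coverage vector of one chromosome from run-length intervals
oracle_perbase <- function(runs, chrom, chrom_len) {
  v <- numeric(chrom_len)
  r <- runs[runs$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r)))
    v[(r$start[i] + 1):r$end[i]] <- v[(r$start[i] + 1):r$end[i]] + r$value[i]
  v
}

# mean coverage over [a, b) (possibly fractional bounds, clamped to the
# chromosome) by weighting each base's overlap with the window
oracle_window_mean <- function(perbase, a, b) {
  width <- b - a
  lo <- max(a, 0); hi <- min(b, length(perbase))
  if (hi <= lo) return(0)
  total <- 0
  p <- floor(lo)
  while (p < hi) {
    w <- min(p + 1, hi) - max(p, lo)
    total <- total + perbase[p + 1] * w
    p <- p + 1
  }
  total / width
}

# scale-regions row for one gene by per-base window means
oracle_matrix_row <- function(perbase, start, end, strand, layout) {
  n_up <- layout$upstream / layout$flank_bin
  n_dn <- layout$downstream / layout$flank_bin
  nb <- layout$body_bins
  edges <- c(seq(start - layout$upstream, start, by = layout$flank_bin),
             start + (end - start) * seq_len(nb - 1) / nb,
             seq(end, end + layout$downstream, by = layout$flank_bin))
  vals <- vapply(seq_len(length(edges) - 1), function(i)
    oracle_window_mean(perbase, edges[i], edges[i + 1]), 0)
  if (strand == "-") rev(vals) else vals
}

# all-pairs universe filter: occupied AND length > min_len AND every other
# gene on the chromosome at least min_gap away (overlap = gap 0)
oracle_filter <- function(genes, occupied, min_len = 2000, min_gap = 2000) {
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!(g$gene_id %in% occupied)) next
    if ((g$end - g$start) <= min_len) next
    ok <- TRUE
    for (j in seq_len(nrow(genes))) {
      if (i == j || genes$chrom[j] != g$chrom) next
      gap <- max(max(genes$start[j], g$start) - min(genes$end[j], g$end), 0)
      if (gap < min_gap) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  genes$gene_id[keep]
}

# exact two-sided rank-sum p by enumerating all group assignments;
# statistic is the Mann-Whitney U of the first group, two-sided p is
# 2 * min(P(U <= u), P(U >= u)) capped at 1 (R's convention)
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  list(statistic = u_obs, p = min(p, 1))
}

# random toy annotation on a couple of chromosomes for filter fuzzing
random_toy_annotation <- function(n_genes, chrom_len = 60000) {
  chroms <- sample(c("cA", "cB"), n_genes, replace = TRUE)
  start <- sample.int(chrom_len - 5000, n_genes, replace = TRUE)
  len <- sample(c(sample(200:1999, n_genes, replace = TRUE),
                  sample(2001:6000, n_genes, replace = TRUE)), n_genes)
  genes <- data.frame(
    gene_id = sprintf("t%03d", seq_len(n_genes)),
    chrom = chroms, start = start, end = start + len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  genome_annotation(genes, c(cA = chrom_len + 10000, cB = chrom_len + 10000))
}

# small uniform-coverage track helper
uniform_track <- function(value, chrom_len, chrom = "chr1", sample_id = "s",
                          namespace = "target", total_fragments = NA_real_) {
  coverage_track(data.frame(chrom = chrom, start = 0, end = chrom_len,
                            value = value),
                 stats::setNames(chrom_len, chrom), sample_id, namespace,
                 total_fragments)
}

# correlation-recovery panel design: one dominant cluster, homogeneous high
# baseline so pseudocount attenuation is uniform across genes
panel_design <- function(cluster, rho, seed, n_genes = 305) {
  props <- if (cluster == "III") c(I = 0.003, II = 0.003, III = 0.994)
           else c(I = 0.99, II = 0.005, III = 0.005)
  simulation_design(
    n_genes = n_genes, cluster_props = props,
    frac_short = 0.003, frac_close = 0.007, frac_unoccupied = 0.003,
    rho_latent = rho, weight_sdlog = 0.1, cluster3_weight_boost = 10,
    effect_sd_c3 = 0.45, seed = seed)
}

# measured rank correlation between AFF4 and polII body median ratios for
# the genes of one planted cluster
panel_measured_rho <- function(cluster, rho, seed) {
  d <- panel_design(cluster, rho, seed)
  sim <- simulate_dataset(d)
  ids <- sim$truth$gene_id[sim$truth$label == cluster]
  a <- modality_median_ratios(sim$chip$tracks, sim$chip$sheet,
                              sim$annotation, ids, "AFF4")
  p <- modality_median_ratios(sim$chip$tracks, sim$chip$sheet,
                              sim$annotation, ids, "polII")
  stats::cor(rank(a), rank(p))
}
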