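# Deterministic synthetic-data generator. Emulates cortex ChIP-seq for
# three modalities (AFF4, total polII, Ser2-phosphorylated polII) in
# matched WT/null animal pairs with exogenous spike-in chromatin at known
# per-sample depths, plus RNA-seq replicates, over an annotation carrying a
# planted three-cluster differential-occupancy structure:
#   cluster I   - polII depleted at the TSS only; AFF4 flank changes of
#                 mixed sign; pSer2 unchanged (paused genes)
#   cluster II  - polII depleted at TSS, gene body and beyond the TES;
#                 pSer2 depleted mostly downstream of the TES
#   cluster III - AFF4 depleted at TSS and body; strongest polII and pSer2
#                 body depletion; highest baseline occupancy and expression
# Fragment counts per gene region are negative binomial; every output is a
# pure function of (design, seed).

.default_effects <- function() {
  # null/WT occupancy multipliers per cluster x modality x region
  mk <- function(up = 1, tss = 1, body = 1, tes = 1, down = 1)
    c(upstream = up, tss = tss, body = body, tes = tes, downstream = down)
  list(
    I = list(AFF4 = mk(), polII = mk(tss = 0.65), pS2polII = mk()),
    II = list(AFF4 = mk(),
              polII = mk(tss = 0.65, body = 0.55, tes = 0.55, down = 0.55),
              pS2polII = mk(body = 0.70, tes = 0.50, down = 0.55)),
    III = list(AFF4 = mk(tss = 0.50, body = 0.50),
               polII = mk(tss = 0.65, body = 0.35, tes = 0.50, down = 0.50),
               pS2polII = mk(body = 0.35, tes = 0.50, down = 0.50)),
    filtered_out = list(AFF4 = mk(), polII = mk(), pS2polII = mk()))
}

# per-modality expected fragment mass per region (sums to 1); the
# pausing_index parameter sets how TSS-heavy total polII is relative to its
# gene body
.region_masses <- function(pausing_index = 3) {
  pol2 <- c(upstream = 0.05, tss = 0.15 * pausing_index, body = 0.45,
            tes = 0.10, downstream = 0.05)
  m <- list(
    AFF4 = c(upstream = 0.15, tss = 0.30, body = 0.30, tes = 0.10, downstream = 0.15),
    polII = pol2 / sum(pol2),
    pS2polII = c(upstream = 0.05, tss = 0.10, body = 0.50, tes = 0.15, downstream = 0.20))
  m
}

#' Simulation design
#'
#' All knobs of the synthetic-data generator, with defaults chosen to
#' emulate the study conditions: 3 matched WT/null animal pairs for each of
#' 3 ChIP modalities, 6 RNA-seq replicates per genotype, spike-in fragments
#' at known per-sample depth multipliers, and planted cluster proportions
#' 0.242/0.720/0.038 of the analysis universe.
#'
#' @param n_genes number of genes.
#' @param chrom,chrom_length target chromosome name and length (`NULL`
#'   length = sized automatically to fit the genes).
#' @param cluster_props named proportions of the universe for clusters
#'   I/II/III (must sum to 1).
#' @param frac_short fraction of genes planted shorter than 2 kb (fail the
#'   length filter).
#' @param frac_close fraction of genes planted closer than 2 kb to a
#'   neighbour (fail the gap filter); placed in adjacent groups so no
#'   universe gene is collateral damage.
#' @param frac_unoccupied fraction of genes with near-zero occupancy (fail
#'   the occupancy filter).
#' @param n_pairs matched ChIP animal pairs per modality.
#' @param n_rna_reps RNA-seq replicates per genotype.
#' @param depth expected ChIP fragments per unit-weight gene per sample.
#' @param fragment_length fragment length, bp (converts counts to
#'   coverage).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param pausing_index TSS/body mass ratio knob for total polII.
#' @param effects nested list of null/WT multipliers per cluster, modality
#'   and region (see `occudiff:::.default_effects`).
#' @param effect_jitter_sd per-gene log2 jitter around the cluster
#'   multipliers.
#' @param aff4_flank_sd log2 SD of the zero-mean mixed-sign AFF4 flank
#'   effect planted in clusters I and II (one sign per gene, shared by both
#'   flanks).
#' @param effect_sd_c3 log2 SD of the per-gene cluster III AFF4-body and
#'   polII-body effects around their cluster multipliers.
#' @param rho_latent planted correlation between the cluster III per-gene
#'   AFF4-body and polII-body effects (both load on one latent score).
#' @param pol2_body_sign_fraction if non-`NULL`, replaces the per-gene
#'   polII gene-body effect for every universe gene with a planted-sign
#'   draw: this fraction of genes decreased (log2 effect
#'   `-(0.3 + Exp(mean 0.35))`), the rest increased.
#' @param cluster3_weight_boost baseline-occupancy/expression multiplier
#'   for cluster III genes.
#' @param weight_sdlog log-normal SD of per-gene baseline weights.
#' @param min_occupied_weight floor on the baseline weight of every
#'   polymerase-occupied gene, keeping planted occupied genes clearly above
#'   the occupancy-detection threshold (the unoccupied class sits far below
#'   it).
#' @param spikein_fragments expected spike-in fragments at multiplier 1.
#' @param spikein_multipliers per-sample efficiency multipliers (recycled
#'   per modality over samples ordered pair1 WT, pair1 null, pair2 WT, ...);
#'   they scale target and spike-in depth together, so spike-in
#'   normalization should undo them.
#' @param spikein_noise draw realized spike-in counts as Poisson (else
#'   exact rounded means).
#' @param spike_chrom,spike_chrom_length spike-in genome namespace.
#' @param region_halfwidth,flank_extent geometry of the signal regions
#'   (TSS/TES half-width and flank extent, bp).
#' @param rna_depth expected RNA counts per unit-weight gene.
#' @param rna_dispersion RNA negative-binomial dispersion.
#' @param rna_multipliers named null/WT expression multipliers per cluster.
#' @param rna_jitter_sd per-gene log2 jitter of the expression effect.
#' @param seed integer seed fixing all randomness.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000,
                              chrom = "chr1", chrom_length = NULL,
                              cluster_props = c(I = 0.242, II = 0.720, III = 0.038),
                              frac_short = 0.10, frac_close = 0.10,
                              frac_unoccupied = 0.05,
                              n_pairs = 3, n_rna_reps = 6,
                              depth = 400, fragment_length = 200,
                              dispersion = 0.015,
                              pausing_index = 3,
                              effects = .default_effects(),
                              effect_jitter_sd = 0.12,
                              aff4_flank_sd = 0.5,
                              effect_sd_c3 = 0.3,
                              rho_latent = 0.35,
                              pol2_body_sign_fraction = NULL,
                              cluster3_weight_boost = 2.5,
                              weight_sdlog = 0.4,
                              min_occupied_weight = 0.6,
                              spikein_fragments = 50000,
                              spikein_multipliers = c(1.0, 0.8, 1.25, 0.9, 1.1, 0.95),
                              spikein_noise = TRUE,
                              spike_chrom = "spike_chr", spike_chrom_length = 1e5,
                              region_halfwidth = 250, flank_extent = 2000,
                              rna_depth = 200, rna_dispersion = 0.05,
                              rna_multipliers = c(I = 1.05, II = 0.85, III = 0.60),
                              rna_jitter_sd = 0.10,
                              seed = 1) {
  if (n_genes < 10) .stopf("n_genes must be >= 10")
  if (abs(sum(cluster_props) - 1) > 1e-8 || any(cluster_props <= 0))
    .stopf("cluster_props must be positive and sum to 1")
  if (frac_short + frac_close + frac_unoccupied >= 1)
    .stopf("filtered-out fractions leave no universe genes")
  if (depth <= 0) .stopf("sequencing depth must be > 0")
  if (dispersion <= 0 || rna_dispersion <= 0) .stopf("dispersion must be > 0")
  if (any(spikein_multipliers <= 0)) .stopf("spike-in multipliers must be > 0")
  if (!is.null(pol2_body_sign_fraction) &&
      (pol2_body_sign_fraction < 0 || pol2_body_sign_fraction > 1))
    .stopf("pol2_body_sign_fraction must be in [0, 1]")
  structure(as.list(environment()), class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("simulation_design: %d genes, %d ChIP pairs x 3 modalities, %d RNA reps/genotype, seed %d\n",
              x$n_genes, x$n_pairs, x$n_rna_reps, x$seed))
  invisible(x)
}

#' Generate an annotation with planted cluster truth
#'
#' Genes are laid along one chromosome with heavy-tailed (log-normal)
#' lengths and intergenic gaps >= 2 kb, except for planted filter
#' violations: an exact `frac_short` fraction shorter than 2 kb, an exact
#' `frac_close` fraction placed in adjacent groups less than 2 kb apart,
#' and a `frac_unoccupied` fraction given near-zero occupancy weight. The
#' remaining genes form the intended analysis universe and carry planted
#' cluster labels I/II/III at the design proportions.
#'
#' @param design a `simulation_design`.
#' @return List with `annotation` (a `genome_annotation`) and `truth`
#'   (data.frame: `gene_id`, `type`, `in_universe`, `label`, `weight`,
#'   `latent`).
#' @export
generate_annotation <- function(design) {
  d <- design
  .with_seed(d$seed, {
    n <- d$n_genes
    n_short <- round(d$frac_short * n)
    n_close <- round(d$frac_close * n)
    if (n_close == 1) n_close <- 2   # close genes need a partner
    n_unocc <- round(d$frac_unoccupied * n)
    idx <- sample.int(n)
    type <- rep("universe", n)
    type[idx[seq_len(n_short)]] <- "short"
    type[idx[n_short + seq_len(n_close)]] <- "close"
    type[idx[n_short + n_close + seq_len(n_unocc)]] <- "unoccupied"

    lens <- integer(n)
    short <- type == "short"
    lens[short] <- sample(500:1900, sum(short), replace = TRUE)
    lens[!short] <- pmin(pmax(round(stats::rlnorm(sum(!short), log(6000), 0.8)),
                              2100), 100000)

    # placement order: "close" genes travel in chunks of 2 (one of 3 when
    # odd) separated internally by sub-2 kb gaps; chunks and all other
    # genes are shuffled as units with >= 2 kb gaps between units
    close_idx <- which(type == "close")
    chunks <- list()
    if (length(close_idx)) {
      nc <- length(close_idx)
      splits <- split(close_idx, ceiling(seq_len(nc) / 2))
      if (nc %% 2 == 1 && length(splits) > 1) {
        splits[[length(splits) - 1]] <- c(splits[[length(splits) - 1]],
                                          splits[[length(splits)]])
        splits[[length(splits)]] <- NULL
      }
      chunks <- splits
    }
    units <- c(chunks, as.list(which(type != "close")))
    units <- units[sample.int(length(units))]
    order_idx <- unlist(units, use.names = FALSE)
    within_chunk <- unlist(lapply(units, function(u)
      c(FALSE, rep(TRUE, length(u) - 1))), use.names = FALSE)

    gaps <- ifelse(within_chunk,
                   sample(100:1899, n, replace = TRUE),
                   sample(2000:8000, n, replace = TRUE))
    starts_o <- cumsum(gaps) + c(0, cumsum(lens[order_idx]))[seq_len(n)]
    ends_o <- starts_o + lens[order_idx]
    need <- ends_o[n] + 5000
    if (!is.null(d$chrom_length)) {
      if (d$chrom_length < need)
        .stopf("chromosome length %g too small to place %d genes (need >= %g)",
               d$chrom_length, n, need)
      chrom_len <- d$chrom_length
    } else chrom_len <- need

    starts <- ends <- integer(n)
    starts[order_idx] <- starts_o
    ends[order_idx] <- ends_o
    width <- max(4L, nchar(n))
    ids <- sprintf(paste0("g%0", width, "d"), seq_len(n))
    genes <- data.frame(gene_id = ids, chrom = d$chrom, start = starts,
                        end = ends,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
    sizes <- stats::setNames(chrom_len, d$chrom)
    ann <- genome_annotation(genes, sizes, "target")

    in_univ <- type == "universe"
    n_univ <- sum(in_univ)
    n_I <- round(d$cluster_props[["I"]] * n_univ)
    n_II <- round(d$cluster_props[["II"]] * n_univ)
    n_III <- n_univ - n_I - n_II
    if (n_III < 1) .stopf("cluster III is empty; adjust proportions or n_genes")
    lab_pool <- sample(c(rep("I", n_I), rep("II", n_II), rep("III", n_III)))
    label <- rep("filtered_out", n)
    label[in_univ] <- lab_pool
    weight <- pmax(stats::rlnorm(n, 0, d$weight_sdlog), d$min_occupied_weight)
    weight[label == "III"] <- weight[label == "III"] * d$cluster3_weight_boost
    weight[type == "unoccupied"] <- weight[type == "unoccupied"] * 0.02
    truth <- data.frame(gene_id = ids, type = type, in_universe = in_univ,
                        label = label, weight = weight,
                        latent = stats::rnorm(n), stringsAsFactors = FALSE)
    list(annotation = ann, truth = truth)
  })
}

# strand-oriented signal regions of one set of genes; returns a long
# data.frame of (gene row, region, start, end); body falls back into the
# TSS window for genes too short to host one (filtered-out genes only)
.gene_region_table <- function(genes, halfwidth, flank) {
  plus <- genes$strand == "+"
  t0 <- ifelse(plus, genes$start, genes$end)
  t1 <- ifelse(plus, genes$end, genes$start)
  body_lo <- pmin(genes$start + halfwidth, genes$end)
  body_hi <- pmax(genes$end - halfwidth, body_lo)
  data.frame(
    row = rep(seq_len(nrow(genes)), times = 5),
    region = rep(c("upstream", "tss", "body", "tes", "downstream"),
                 each = nrow(genes)),
    start = c(ifelse(plus, t0 - flank, t0), t0 - halfwidth, body_lo,
              t1 - halfwidth, ifelse(plus, t1, t1 - flank)),
    end = c(ifelse(plus, t0, t0 + flank), t0 + halfwidth, body_hi,
            t1 + halfwidth, ifelse(plus, t1 + flank, t1)),
    stringsAsFactors = FALSE)
}

# per-gene log2 effect deviations (gene x modality x region), drawn once
# per experiment; cluster III AFF4-body and polII-body share the latent
# score from the truth table
.draw_effect_devs <- function(truth, d) {
  n <- nrow(truth)
  regions <- c("upstream", "tss", "body", "tes", "downstream")
  dev <- array(stats::rnorm(n * 3 * 5, sd = d$effect_jitter_sd),
               dim = c(n, 3, 5),
               dimnames = list(truth$gene_id, .modalities_chip, regions))
  mixed <- truth$label %in% c("I", "II")
  z_flank <- stats::rnorm(n, sd = d$aff4_flank_sd)
  dev[mixed, "AFF4", "upstream"] <- z_flank[mixed]
  dev[mixed, "AFF4", "downstream"] <- z_flank[mixed]
  c3 <- truth$label == "III"
  if (any(c3)) {
    r <- d$rho_latent
    e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
    a <- sqrt(r) * truth$latent + sqrt(1 - r) * e1
    p <- sqrt(r) * truth$latent + sqrt(1 - r) * e2
    dev[c3, "AFF4", "body"] <- d$effect_sd_c3 * a[c3]
    dev[c3, "polII", "body"] <- d$effect_sd_c3 * p[c3]
  }
  dev
}

#' Simulate the ChIP experiment (target + spike-in coverage)
#'
#' For each modality, `n_pairs` matched WT/null sample pairs are drawn.
#' Fragment counts per gene region are negative binomial with mean
#' depth x gene weight x region mass x sample multiplier x effect, where
#' the null-genotype effect combines the planted cluster multiplier with
#' per-gene log2 deviations. The TSS mass sits in a discretized 150 bp
#' bell; other regions are uniform. Spike-in tracks carry fragments
#' proportional to the per-sample multiplier, so true scale factors are
#' known.
#'
#' @param annotation,truth output of [generate_annotation()].
#' @param design the same `simulation_design`.
#' @return List with `tracks` (per sample id: list(`target`, `spikein`)),
#'   `sheet` (a `sample_sheet` with fragment counts, no paths),
#'   `true_multipliers` and `true_factors` (named per sample),
#'   `effect_log2` (gene x modality x region array of planted null/WT
#'   log2 effects).
#' @export
simulate_chip_experiment <- function(annotation, truth, design) {
  d <- design
  if (!identical(annotation$genes$gene_id, truth$gene_id))
    .stopf("truth does not match annotation")
  if (d$depth <= 0) .stopf("sequencing depth must be > 0")
  .with_seed(d$seed + 1, {
    genes <- annotation$genes
    n <- nrow(genes)
    regions <- c("upstream", "tss", "body", "tes", "downstream")
    masses <- .region_masses(d$pausing_index)
    dev <- .draw_effect_devs(truth, d)

    # planted log2(null/WT) effect per gene x modality x region
    eff <- array(0, dim = dim(dev), dimnames = dimnames(dev))
    for (m in .modalities_chip)
      for (r in regions) {
        mult <- vapply(truth$label, function(l) d$effects[[l]][[m]][[r]], 0)
        eff[, m, r] <- log2(mult) + dev[, m, r]
      }
    if (!is.null(d$pol2_body_sign_fraction)) {
      univ <- which(truth$in_universe)
      n_dec <- round(d$pol2_body_sign_fraction * length(univ))
      dec <- univ[sample.int(length(univ), n_dec)]
      mag <- 0.3 + stats::rexp(length(univ), rate = 1 / 0.35)
      sgn <- ifelse(univ %in% dec, -1, 1)
      eff[univ, "polII", "body"] <- sgn * mag
    }

    reg_tab <- .gene_region_table(genes, d$region_halfwidth, d$flank_extent)
    # split the TSS window mass into a 150 bp discretized bell around the
    # TSS (25/50/25% over three 50 bp sub-bins)
    t0 <- ifelse(genes$strand == "+", genes$start, genes$end)

    n_samp_per_mod <- 2 * d$n_pairs
    mult <- rep_len(d$spikein_multipliers, n_samp_per_mod)
    rows <- list(); tracks <- list()
    true_mult <- true_fact <- numeric(0)
    for (m in .modalities_chip) {
      mass <- masses[[m]]
      k <- 0
      for (p in seq_len(d$n_pairs)) for (gt in .genotypes) {
        k <- k + 1
        sid <- sprintf("%s_p%d_%s", m, p, gt)
        eps <- mult[k]
        mu_gene <- d$depth * truth$weight * eps
        counts <- matrix(0, n, 5, dimnames = list(NULL, regions))
        for (r in regions) {
          mu <- mu_gene * mass[[r]]
          if (gt == "null") mu <- mu * 2^eff[, m, r]
          counts[, r] <- stats::rnbinom(n, mu = mu, size = 1 / d$dispersion)
        }
        # coverage: uniform value per region (TSS bell handled below)
        iv <- reg_tab
        cvals <- counts[cbind(iv$row, match(iv$region, regions))]
        keep <- iv$region != "tss"
        width <- iv$end - iv$start
        val <- ifelse(width > 0, cvals * d$fragment_length / width, 0)
        ivs <- data.frame(start = iv$start[keep], end = iv$end[keep],
                          value = val[keep])
        bell <- data.frame(
          start = c(t0 - 75, t0 - 25, t0 + 25),
          end = c(t0 - 25, t0 + 25, t0 + 75),
          value = rep(counts[, "tss"], 3) * rep(c(0.25, 0.5, 0.25), each = n) *
            d$fragment_length / 50)
        ivs <- rbind(ivs, bell)
        ivs$start <- pmax(ivs$start, 0)
        ivs$end <- pmin(ivs$end, annotation$chrom_sizes[[genes$chrom[1]]])
        runs <- .runs_from_intervals(rep(genes$chrom[1], nrow(ivs)),
                                     ivs$start, ivs$end, ivs$value)
        target <- coverage_track(runs, annotation$chrom_sizes, sid, "target",
                                 total_fragments = sum(counts))
        sp_mean <- d$spikein_fragments * eps
        sp_n <- if (d$spikein_noise) stats::rpois(1, sp_mean) else round(sp_mean)
        sp_runs <- data.frame(chrom = d$spike_chrom, start = 0,
                              end = d$spike_chrom_length,
                              value = sp_n * d$fragment_length / d$spike_chrom_length)
        spike <- coverage_track(sp_runs,
                                stats::setNames(d$spike_chrom_length, d$spike_chrom),
                                sid, "spikein", total_fragments = sp_n)
        tracks[[sid]] <- list(target = target, spikein = spike)
        rows[[sid]] <- data.frame(sample_id = sid, genotype = gt, modality = m,
                                  pair_id = sprintf("p%d", p),
                                  target_path = "", spikein_path = "",
                                  target_fragments = sum(counts),
                                  spikein_fragments = sp_n,
                                  stringsAsFactors = FALSE)
        true_mult[sid] <- eps
      }
      ids <- names(true_mult)[seq.int(length(true_mult) - k + 1, length(true_mult))]
      true_fact[ids] <- min(true_mult[ids]) / true_mult[ids]
    }
    sheet <- validate_sample_sheet(do.call(rbind, rows))
    list(tracks = tracks, sheet = sheet, true_multipliers = true_mult,
         true_factors = true_fact, effect_log2 = eff)
  })
}

#' Simulate RNA-seq counts
#'
#' `n_rna_reps` replicates per genotype; counts per gene are negative
#' binomial with mean baseline x genotype multiplier. Cluster III carries
#' the highest baseline expression (via the shared weight boost) and the
#' strongest planted decrease; cluster I a slight increase.
#'
#' @param annotation,truth output of [generate_annotation()].
#' @param design the same `simulation_design`.
#' @return List with `expr` (an `expression_table`) and `true_log2fc`
#'   (named per-gene planted expression log2 fold change).
#' @export
simulate_rnaseq_counts <- function(annotation, truth, design) {
  d <- design
  if (!identical(annotation$genes$gene_id, truth$gene_id))
    .stopf("truth does not match annotation")
  if (d$rna_dispersion <= 0) .stopf("dispersion must be > 0")
  .with_seed(d$seed + 2, {
    n <- nrow(truth)
    mult <- ifelse(truth$label == "filtered_out", 1,
                   d$rna_multipliers[truth$label])
    lfc <- log2(mult) + stats::rnorm(n, sd = d$rna_jitter_sd)
    # cluster III expression change loads on the same per-gene latent score
    # as its occupancy change (strongly affected genes lose the most RNA)
    c3 <- truth$label == "III"
    if (any(c3)) {
      r <- d$rho_latent
      dev3 <- d$effect_sd_c3 * (sqrt(r) * truth$latent +
                                sqrt(1 - r) * stats::rnorm(n))
      lfc[c3] <- log2(mult[c3]) + dev3[c3]
    }
    base <- d$rna_depth * truth$weight
    nrep <- d$n_rna_reps
    ids <- c(sprintf("RNA_WT_%d", seq_len(nrep)), sprintf("RNA_null_%d", seq_len(nrep)))
    genotype <- rep(.genotypes, each = nrep)
    counts <- matrix(0L, n, 2 * nrep, dimnames = list(truth$gene_id, ids))
    for (j in seq_len(2 * nrep)) {
      mu <- if (genotype[j] == "null") base * 2^lfc else base
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / d$rna_dispersion)
    }
    list(expr = expression_table(counts, genotype),
         true_log2fc = stats::setNames(lfc, truth$gene_id))
  })
}

#' Simulate a complete dataset in memory
#'
#' @param design a `simulation_design`.
#' @return List: `design`, `annotation`, `truth`, `chip` (from
#'   [simulate_chip_experiment()]) and `rna` (from
#'   [simulate_rnaseq_counts()]).
#' @export
simulate_dataset <- function(design = simulation_design()) {
  ga <- generate_annotation(design)
  chip <- simulate_chip_experiment(ga$annotation, ga$truth, design)
  rna <- simulate_rnaseq_counts(ga$annotation, ga$truth, design)
  list(design = design, annotation = ga$annotation, truth = ga$truth,
       chip = chip, rna = rna)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the file interfaces the pipeline readers consume:
#' BED12 annotation, chrom-sizes files for both namespaces, per-sample
#' target and spike-in bedGraphs, a TSV sample sheet with fragment counts,
#' an RNA count TSV, and the planted truth table.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named list of the file paths written, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) .stopf("output directory not writable: %s", dir)
  d <- sim$design
  paths <- list(
    annotation = file.path(dir, "annotation.bed"),
    chrom_sizes = file.path(dir, "target.chrom.sizes"),
    spike_sizes = file.path(dir, "spikein.chrom.sizes"),
    sample_sheet = file.path(dir, "samples.tsv"),
    counts = file.path(dir, "rna_counts.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_bed12(sim$annotation, paths$annotation)
  .write_chrom_sizes(sim$annotation$chrom_sizes, paths$chrom_sizes)
  .write_chrom_sizes(stats::setNames(d$spike_chrom_length, d$spike_chrom),
                     paths$spike_sizes)
  sheet <- as.data.frame(sim$chip$sheet)
  for (sid in names(sim$chip$tracks)) {
    tgt <- file.path(dir, paste0(sid, ".target.bedgraph"))
    spk <- file.path(dir, paste0(sid, ".spikein.bedgraph"))
    write_bedgraph(sim$chip$tracks[[sid]]$target, tgt)
    write_bedgraph(sim$chip$tracks[[sid]]$spikein, spk)
    sheet$target_path[sheet$sample_id == sid] <- basename(tgt)
    sheet$spikein_path[sheet$sample_id == sid] <- basename(spk)
  }
  rna_rows <- data.frame(
    sample_id = colnames(sim$rna$expr$counts),
    genotype = sim$rna$expr$genotype,
    modality = "RNA", pair_id = "", target_path = "", spikein_path = "",
    target_fragments = NA_real_, spikein_fragments = NA_real_,
    stringsAsFactors = FALSE)
  write_sample_sheet(rbind(sheet, rna_rows), paths$sample_sheet)
  write_expression_counts(sim$rna$expr, paths$counts)
  .write_tsv(sim$truth, paths$truth)
  invisible(paths)
}
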