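# End-to-end orchestration: read inputs -> spike-in normalization -> gene
# universe -> occupancy matrices and per-pair fold changes -> pair selection
# -> clustering and canonical labels -> median-of-ratios summaries ->
# per-cluster correlations -> expression comparison -> TSV/JSON outputs.
# Every output carries the config hash and seed; reruns are byte-identical.

#' Pipeline configuration
#'
#' @param annotation path to a BED/GTF gene annotation.
#' @param chrom_sizes path to the target chrom-sizes file (or named vector).
#' @param spike_chrom_sizes path/vector for the spike-in namespace.
#' @param sample_sheet path to the TSV sample sheet.
#' @param counts path to the RNA count TSV (optional; expression stages are
#'   skipped when absent).
#' @param peaks optional named list (by replicate) of BED peak files for
#'   peaks-mode occupied-gene detection.
#' @param outdir output directory (`NULL` = no files written).
#' @param layout a `region_layout`.
#' @param norm_convention spike-in factor convention (`"min"`, `"mean"`,
#'   `"fixed"`).
#' @param occupied_mode `"threshold"` or `"peaks"`.
#' @param occupied_window,occupied_theta,occupied_quorum occupied-gene
#'   detection parameters (see [detect_occupied_genes()]).
#' @param k number of clusters.
#' @param n_select matched pairs kept for clustering.
#' @param delta pseudocount for ratios and fold changes.
#' @param fragment_length fragment length for area-based fragment counting.
#' @param seed recorded seed (the pipeline itself is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, chrom_sizes, spike_chrom_sizes,
                            sample_sheet, counts = NULL, peaks = NULL,
                            outdir = NULL, layout = region_layout(),
                            norm_convention = "min",
                            occupied_mode = "threshold",
                            occupied_window = 1000, occupied_theta = 2,
                            occupied_quorum = NULL,
                            k = 3, n_select = 2, delta = 1.0,
                            fragment_length = 200, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  for (key in c("annotation", "chrom_sizes", "spike_chrom_sizes",
                "sample_sheet", "counts", "outdir"))
    if (!is.null(y[[key]]) && !grepl("^/", y[[key]]))
      y[[key]] <- file.path(base, y[[key]])
  if (!is.null(y$layout)) y$layout <- do.call(region_layout, y$layout)
  do.call(pipeline_config, y)
}

# stable hash of the analysis settings (md5 of their deparsed canonical
# form); file locations are excluded so moving a dataset does not change
# the hash
.config_hash <- function(config) {
  cfg <- config
  for (key in c("annotation", "chrom_sizes", "spike_chrom_sizes",
                "sample_sheet", "counts", "peaks", "outdir"))
    cfg[[key]] <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full differential-occupancy pipeline
#'
#' Stages: read inputs, per-modality spike-in scale factors, normalized
#' coverage, occupied-gene detection on WT polII, universe filtering,
#' scale-regions matrices and per-pair log2 fold-change matrices, selection
#' of the most-affected pairs, Ward clustering of per-modality TSS/body/TES
#' median fold-change features, canonical I/II/III labels, matched-pair
#' median-of-ratios summaries across all pairs, per-cluster Spearman
#' correlations (AFF4 vs polII body change; AFF4 vs RNA expression change),
#' fraction of genes with decreased polII body occupancy, and the Wilcoxon
#' WT-vs-null comparison of cluster expression.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @return An object of class `occupancy_pipeline`; see
#'   [summary.occupancy_pipeline()]. If `config$outdir` is set, TSV/JSON
#'   outputs are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  hash <- .config_hash(config)
  lay <- config$layout
  for (key in c("annotation", "sample_sheet", "counts")) {
    p <- config[[key]]
    if (!is.null(p) && is.character(p) && !file.exists(p))
      .stopf("pipeline stage 'validate': input file missing (%s: %s)", key, p)
  }

  ann <- .stage("read_annotation",
                read_gene_annotation(config$annotation, config$chrom_sizes))
  sheet <- .stage("read_samples", read_sample_sheet(config$sample_sheet))
  spike_sizes <- config$spike_chrom_sizes
  if (is.character(spike_sizes) && length(spike_sizes) == 1L)
    spike_sizes <- .read_chrom_sizes(spike_sizes)

  chip <- sheet[sheet$modality != "RNA", , drop = FALSE]
  tracks <- .stage("read_coverage", {
    out <- list()
    for (i in seq_len(nrow(chip))) {
      r <- chip[i, ]
      out[[r$sample_id]] <- list(
        target = read_bedgraph(r$target_path, ann$chrom_sizes, "target",
                               r$sample_id, r$target_fragments),
        spikein = read_bedgraph(r$spikein_path, spike_sizes, "spikein",
                                r$sample_id, r$spikein_fragments))
    }
    out
  })

  factors <- .stage("spike_norm", {
    out <- lapply(split(chip$sample_id, chip$modality), function(ids) {
      st <- spikein_stats(
        stats::setNames(lapply(ids, function(s) tracks[[s]]$spikein), ids),
        stats::setNames(lapply(ids, function(s) tracks[[s]]$target), ids),
        fragment_length = config$fragment_length,
        convention = config$norm_convention)
      st$modality <- chip$modality[match(st$sample_id, chip$sample_id)]
      st
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  })
  norm_tracks <- .stage("normalize", {
    out <- list()
    for (i in seq_len(nrow(factors)))
      out[[factors$sample_id[i]]] <-
        normalize_track(tracks[[factors$sample_id[i]]]$target,
                        factors$scale_factor[i])
    out
  })

  universe <- .stage("universe", {
    wt_pol2 <- chip$sample_id[chip$modality == "polII" & chip$genotype == "WT"]
    occupied <- if (config$occupied_mode == "peaks") {
      pk <- lapply(config$peaks, read_peaks)
      detect_occupied_genes(ann, peaks = pk, mode = "peaks",
                            window = config$occupied_window,
                            quorum = config$occupied_quorum)
    } else {
      detect_occupied_genes(ann, tracks = norm_tracks[wt_pol2],
                            mode = "threshold",
                            window = config$occupied_window,
                            theta = config$occupied_theta,
                            quorum = config$occupied_quorum)
    }
    filter_gene_universe(ann, occupied)
  })
  if (universe$n < config$k)
    .stopf("pipeline stage 'universe': only %d genes retained", universe$n)

  matrices <- .stage("matrices", {
    out <- list()
    for (sid in names(norm_tracks))
      out[[sid]] <- build_scaled_matrix(
        norm_tracks[[sid]], ann, universe, lay,
        modality = chip$modality[chip$sample_id == sid])
    out
  })
  fc <- .stage("fold_change", {
    out <- list()
    for (m in unique(chip$modality)) for (p in unique(chip$pair_id)) {
      wt <- chip$sample_id[chip$modality == m & chip$pair_id == p & chip$genotype == "WT"]
      nl <- chip$sample_id[chip$modality == m & chip$pair_id == p & chip$genotype == "null"]
      out[[paste(m, p, sep = ".")]] <-
        pairwise_log2fc(matrices[[nl]], matrices[[wt]], config$delta, pair_id = p)
    }
    out
  })
  selected <- .stage("select_pairs", select_pairs(fc, config$n_select))

  summaries <- .stage("region_summaries", {
    out <- list()
    for (sid in names(norm_tracks))
      out[[sid]] <- summarize_regions(norm_tracks[[sid]], ann, universe, lay)
    out
  })
  sum_by <- function(modality, genotype) {
    ids <- chip[chip$modality == modality & chip$genotype == genotype, ]
    stats::setNames(summaries[ids$sample_id], ids$pair_id)
  }
  ratios <- .stage("median_ratios", {
    out <- list()
    for (m in unique(chip$modality)) for (r in c("tss", "body", "tes"))
      out[[paste(m, r, sep = ".")]] <- median_ratio_per_gene(
        sum_by(m, "null"), sum_by(m, "WT"), region = r, delta = config$delta)
    out
  })

  clusters <- .stage("cluster", {
    feats <- sapply(names(ratios), function(nm) {
      m <- strsplit(nm, ".", fixed = TRUE)[[1]][1]
      r <- strsplit(nm, ".", fixed = TRUE)[[1]][2]
      mr <- median_ratio_per_gene(sum_by(m, "null"), sum_by(m, "WT"),
                                  region = r, delta = config$delta,
                                  pairs = selected)
      log2(mr$median_ratio)
    })
    rownames(feats) <- universe$gene_ids
    asg <- cluster_genes(feats, k = config$k)
    if (config$k == 3)
      asg <- label_clusters(asg, stats::setNames(feats[, "polII.body"],
                                                 rownames(feats)))
    asg
  })
  cluster_labels <- if (!is.null(clusters$canonical)) clusters$canonical
                    else stats::setNames(as.character(clusters$labels),
                                         names(clusters$labels))

  aff4_body <- stats::setNames(ratios[["AFF4.body"]]$median_ratio,
                               ratios[["AFF4.body"]]$gene_id)
  pol2_body <- stats::setNames(ratios[["polII.body"]]$median_ratio,
                               ratios[["polII.body"]]$gene_id)
  correlations <- .stage("correlations",
    spearman_by_cluster(aff4_body, pol2_body, cluster_labels,
                        "AFF4_body_ratio", "polII_body_ratio"))
  frac_dec <- .stage("fraction_decreased", fraction_decreased(pol2_body))

  expr <- NULL; expr_test <- NULL; rna_corr <- NULL
  if (!is.null(config$counts)) {
    expr <- .stage("read_expression",
                   read_expression_counts(config$counts, sheet = sheet))
    expr_test <- .stage("expression_comparison",
                        compare_cluster_expression(expr, cluster_labels,
                                                   delta = config$delta))
    rna_corr <- .stage("rna_correlations", {
      mr <- genotype_mean_rpm(expr)
      idx <- match(universe$gene_ids, mr$gene_id)
      if (anyNA(idx)) .stopf("universe gene(s) missing from counts")
      rna_ratio <- stats::setNames(
        (mr$null[idx] + config$delta) / (mr$WT[idx] + config$delta),
        universe$gene_ids)
      spearman_by_cluster(aff4_body, rna_ratio, cluster_labels,
                          "AFF4_body_ratio", "RNA_ratio")
    })
  }

  res <- structure(list(
    config = config, config_hash = hash, seed = config$seed,
    annotation = ann, sheet = sheet, scale_factors = factors,
    universe = universe, matrices = matrices, fold_changes = fc,
    selected_pairs = selected, median_ratios = ratios,
    clusters = clusters, cluster_labels = cluster_labels,
    correlations = correlations, rna_correlations = rna_corr,
    fraction_pol2_decreased = frac_dec,
    expression = expr, expression_test = expr_test),
    class = "occupancy_pipeline")
  if (!is.null(config$outdir))
    .stage("write_outputs", write_pipeline_outputs(res, config$outdir))
  res
}

#' Write pipeline outputs to a directory
#'
#' Universe outcomes, scale factors, cluster assignment, per-cluster
#' correlations, median-ratio tables and a JSON summary; every file carries
#' `seed` and `config_hash` header comments. Outputs are byte-stable for a
#' fixed config and inputs.
#'
#' @param result an `occupancy_pipeline`.
#' @param outdir output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hdr <- c(sprintf("seed=%d", result$seed),
           sprintf("config_hash=%s", result$config_hash))
  paths <- list()
  paths$universe <- write_universe(result$universe,
                                   file.path(outdir, "universe.tsv"), hdr)
  paths$factors <- .write_tsv(result$scale_factors,
                              file.path(outdir, "scale_factors.tsv"), hdr)
  cl <- data.frame(gene_id = names(result$cluster_labels),
                   cluster = unname(result$cluster_labels),
                   stringsAsFactors = FALSE)
  paths$clusters <- .write_tsv(cl, file.path(outdir, "clusters.tsv"), hdr)
  paths$correlations <- .write_tsv(result$correlations,
                                   file.path(outdir, "correlations.tsv"), hdr)
  for (nm in names(result$median_ratios))
    paths[[paste0("ratios_", nm)]] <- .write_tsv(
      result$median_ratios[[nm]],
      file.path(outdir, sprintf("median_ratios_%s.tsv", nm)), hdr)
  if (!is.null(result$rna_correlations))
    paths$rna_correlations <- .write_tsv(
      result$rna_correlations, file.path(outdir, "rna_correlations.tsv"), hdr)
  if (!is.null(result$expression_test))
    paths$expression_test <- .write_tsv(
      result$expression_test, file.path(outdir, "expression_wilcoxon.tsv"), hdr)
  summary_json <- list(
    seed = result$seed, config_hash = result$config_hash,
    n_universe = result$universe$n,
    cluster_sizes = as.list(table(result$cluster_labels)),
    selected_pairs = as.list(result$selected_pairs),
    fraction_pol2_decreased = result$fraction_pol2_decreased)
  paths$summary <- file.path(outdir, "summary.json")
  writeLines(.to_json(summary_json), paths$summary)
  invisible(paths)
}

# minimal JSON serializer for the summary file (scalars, vectors, lists)
.to_json <- function(x, indent = "") {
  if (is.list(x)) {
    if (is.null(names(x))) {
      items <- vapply(x, .to_json, "", indent = paste0(indent, "  "))
      paste0("[", paste(items, collapse = ", "), "]")
    } else {
      items <- vapply(seq_along(x), function(i)
        sprintf("\"%s\": %s", names(x)[i],
                .to_json(x[[i]], paste0(indent, "  "))), "")
      paste0("{", paste(items, collapse = ", "), "}")
    }
  } else if (is.character(x)) {
    if (length(x) > 1) .to_json(as.list(x)) else sprintf("\"%s\"", x)
  } else {
    if (length(x) > 1) .to_json(as.list(x))
    else format(x, digits = 15, scientific = FALSE)
  }
}

#' @export
print.occupancy_pipeline <- function(x, ...) {
  cat("occupancy_pipeline result\n")
  cat(sprintf("  universe: %d genes; selected pairs: %s\n",
              x$universe$n, paste(x$selected_pairs, collapse = ", ")))
  tab <- table(x$cluster_labels)
  cat(sprintf("  clusters: %s\n",
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  fraction of genes with decreased polII body occupancy: %.3f\n",
              x$fraction_pol2_decreased))
  invisible(x)
}

#' Summarize a pipeline result
#'
#' @param object an `occupancy_pipeline`.
#' @param ... unused.
#' @return The object, invisibly; prints universe, factors, cluster sizes,
#'   correlations and expression comparison.
#' @export
summary.occupancy_pipeline <- function(object, ...) {
  print(object)
  cat("\nspike-in scale factors:\n")
  print(object$scale_factors, row.names = FALSE)
  cat("\nper-cluster Spearman correlations (AFF4 vs polII body change):\n")
  print(object$correlations, row.names = FALSE)
  if (!is.null(object$rna_correlations)) {
    cat("\nper-cluster Spearman correlations (AFF4 vs RNA expression change):\n")
    print(object$rna_correlations, row.names = FALSE)
  }
  if (!is.null(object$expression_test)) {
    cat("\ncluster expression WT vs null (Wilcoxon rank sum):\n")
    print(object$expression_test, row.names = FALSE)
  }
  invisible(object)
}

#' Simulate a dataset and run the pipeline on its file interfaces
#'
#' Convenience for end-to-end validation: writes a synthetic dataset to
#' `dir`, builds a matching config, and runs [run_pipeline()] on the files.
#'
#' @param design a `simulation_design`.
#' @param dir dataset/output directory.
#' @param ... overrides passed to [pipeline_config()].
#' @return List with `sim` (the dataset) and `result` (the pipeline run).
#' @export
run_synthetic_pipeline <- function(design = simulation_design(), dir = tempfile("occudiff_"),
                                   ...) {
  sim <- simulate_dataset(design)
  paths <- write_dataset(sim, dir)
  cfg <- pipeline_config(
    annotation = paths$annotation, chrom_sizes = paths$chrom_sizes,
    spike_chrom_sizes = paths$spike_sizes, sample_sheet = paths$sample_sheet,
    counts = paths$counts, outdir = file.path(dir, "out"),
    seed = design$seed, ...)
  list(sim = sim, result = run_pipeline(cfg))
}
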