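# Convenience wrappers for modality-level analyses on in-memory tracks
# (the same steps run_pipeline() performs on files).

#' Spike-in normalized region summaries for one modality
#'
#' Computes spike-in scale factors for the samples of one modality,
#' normalizes their target tracks, and returns per-sample region summaries
#' keyed for matched-pair analysis.
#'
#' @param tracks named list (by sample id) of `list(target, spikein)`
#'   coverage-track pairs, e.g. from [simulate_chip_experiment()].
#' @param sheet a `sample_sheet` covering the samples.
#' @param annotation a `genome_annotation`.
#' @param genes gene ids (or a `gene_universe`) to summarize.
#' @param modality which modality to process.
#' @param layout a `region_layout`.
#' @param convention spike-in factor convention.
#' @return List with `factors` (data.frame) and `null`/`wt` (named-by-pair
#'   lists of region-summary data.frames).
#' @export
modality_region_summaries <- function(tracks, sheet, annotation, genes,
                                      modality, layout = region_layout(),
                                      convention = "min") {
  sub <- as.data.frame(sheet)[sheet$modality == modality, , drop = FALSE]
  if (!nrow(sub)) .stopf("no samples for modality %s", modality)
  st <- data.frame(sample_id = sub$sample_id,
                   spikein_fragments = vapply(sub$sample_id, function(s)
                     count_spikein_fragments(tracks[[s]]$spikein), 0),
                   stringsAsFactors = FALSE)
  st <- compute_scale_factors(st, convention = convention)
  sums <- list()
  for (i in seq_len(nrow(sub))) {
    sid <- sub$sample_id[i]
    tr <- normalize_track(tracks[[sid]]$target,
                          st$scale_factor[st$sample_id == sid])
    sums[[sid]] <- summarize_regions(tr, annotation, genes, layout)
  }
  by_gt <- function(gt) {
    ids <- sub[sub$genotype == gt, ]
    stats::setNames(sums[ids$sample_id], ids$pair_id)
  }
  list(factors = st, null = by_gt("null"), wt = by_gt("WT"))
}

#' Matched-pair median ratios for one modality and region
#'
#' One-call wrapper: [modality_region_summaries()] followed by
#' [median_ratio_per_gene()].
#'
#' @inheritParams modality_region_summaries
#' @param region `"tss"`, `"body"` or `"tes"` (or a flank).
#' @param delta pseudocount.
#' @return Named numeric vector of per-gene median null/WT ratios.
#' @export
modality_median_ratios <- function(tracks, sheet, annotation, genes, modality,
                                   region = "body", delta = 1.0,
                                   layout = region_layout(), convention = "min") {
  ms <- modality_region_summaries(tracks, sheet, annotation, genes, modality,
                                  layout, convention)
  mr <- median_ratio_per_gene(ms$null, ms$wt, region = region, delta = delta)
  stats::setNames(mr$median_ratio, mr$gene_id)
}
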