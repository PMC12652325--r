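# Exogenous spike-in normalization. Each ChIP sample carries chromatin from
# a second genome at (ideally) constant mass, so its spike-in fragment count
# tracks the sample's overall recovery/sequencing efficiency. Scaling target
# coverage by a factor inversely proportional to the spike-in count makes
# occupancy comparable across samples. Normalization groups are per modality
# (different spike-in masses per antibody).

#' Count spike-in fragments in a track
#'
#' Uses the recorded `total_fragments` when present; otherwise estimates
#' count = coverage area / fragment_length, rounded to the nearest integer.
#'
#' @param track a `coverage_track` with namespace `"spikein"`.
#' @param fragment_length assumed fragment length (bp) for the area fallback.
#' @return A non-negative count (zero is legal; downstream normalization
#'   rejects it).
#' @export
count_spikein_fragments <- function(track, fragment_length = 200) {
  if (!inherits(track, "coverage_track")) .stopf("track must be a coverage_track")
  if (track$namespace != "spikein")
    .stopf("track '%s' has namespace '%s', expected 'spikein'",
           track$sample_id, track$namespace)
  if (!is.na(track$total_fragments)) return(track$total_fragments)
  .check_scalar_num(fragment_length, "fragment_length", positive = TRUE)
  round(coverage_area(track) / fragment_length)
}

#' Compute per-sample spike-in scale factors
#'
#' Within one normalization group (one modality), the default
#' reference-to-minimum convention sets
#' `factor_i = min_j(spikein_j) / spikein_i`, so the sample with the fewest
#' spike-in fragments keeps factor 1 and every other sample is scaled down.
#' Alternatives: `"mean"` (mean_j / spikein_i, may upscale) and `"fixed"`
#' (reference / spikein_i for a supplied reference count).
#'
#' @param stats data.frame with columns `sample_id` and `spikein_fragments`
#'   (optionally `target_fragments`).
#' @param convention `"min"`, `"mean"` or `"fixed"`.
#' @param reference reference count for `convention = "fixed"`.
#' @return The input data.frame with a `scale_factor` column appended.
#' @export
compute_scale_factors <- function(stats, convention = c("min", "mean", "fixed"),
                                  reference = NULL) {
  convention <- match.arg(convention)
  if (!all(c("sample_id", "spikein_fragments") %in% names(stats)))
    .stopf("stats needs columns sample_id and spikein_fragments")
  s <- stats$spikein_fragments
  if (any(is.na(s)))
    .stopf("missing spike-in fragment count for sample(s): %s",
           paste(stats$sample_id[is.na(s)], collapse = ", "))
  if (any(s <= 0))
    .stopf("sample(s) with zero spike-in fragments cannot be normalized: %s",
           paste(stats$sample_id[s <= 0], collapse = ", "))
  ref <- switch(convention,
                min = min(s),
                mean = mean(s),
                fixed = {
                  if (is.null(reference)) .stopf("convention 'fixed' needs a reference count")
                  .check_scalar_num(reference, "reference", positive = TRUE)
                })
  stats$scale_factor <- ref / s
  stats
}

#' Spike-in statistics for a set of samples
#'
#' Convenience wrapper: counts spike-in (and target) fragments for each
#' sample of one modality and computes scale factors.
#'
#' @param spikein_tracks named list of spike-in `coverage_track`s
#'   (names = sample ids).
#' @param target_tracks optional matching list of target tracks (for the
#'   reported `target_fragments` column).
#' @param fragment_length fragment length for area-based counting.
#' @param convention passed to [compute_scale_factors()].
#' @return data.frame: `sample_id`, `target_fragments`, `spikein_fragments`,
#'   `scale_factor`.
#' @export
spikein_stats <- function(spikein_tracks, target_tracks = NULL,
                          fragment_length = 200, convention = "min") {
  ids <- names(spikein_tracks)
  if (is.null(ids)) ids <- vapply(spikein_tracks, `[[`, "", "sample_id")
  tf <- rep(NA_real_, length(ids))
  if (!is.null(target_tracks))
    tf <- vapply(target_tracks, function(t)
      if (is.na(t$total_fragments)) round(coverage_area(t) / fragment_length)
      else t$total_fragments, 0)
  df <- data.frame(
    sample_id = ids,
    target_fragments = tf,
    spikein_fragments = vapply(spikein_tracks, count_spikein_fragments, 0,
                               fragment_length = fragment_length),
    row.names = NULL, stringsAsFactors = FALSE)
  compute_scale_factors(df, convention = convention)
}
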