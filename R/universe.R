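# Analysis gene universe: polymerase-occupied genes that are long enough and
# far enough from their neighbours for window-based occupancy quantification
# to be meaningful. Three filters: (i) RNA pol II occupied (WT samples only),
# (ii) gene length strictly greater than 2 kb, (iii) nearest neighbouring
# gene span at least 2 kb away (strand-ignored; overlap counts as gap 0).

#' Read BED peak calls
#' @param path BED file (>= 3 columns).
#' @return data.frame with columns `chrom`, `start`, `end` (possibly empty).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) .stopf("peak file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines[keep], "[ \t]+")
  if (any(lengths(fields) < 3)) .stopf("BED peak lines need >= 3 columns in %s", path)
  data.frame(chrom = vapply(fields, `[[`, "", 1L),
             start = as.numeric(vapply(fields, `[[`, "", 2L)),
             end = as.numeric(vapply(fields, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# width-weighted median of nonzero run values (the genome-wide per-base
# median of nonzero coverage)
.median_nonzero_coverage <- function(track) {
  r <- track$runs[track$runs$value > 0, , drop = FALSE]
  if (!nrow(r)) return(0)
  o <- order(r$value)
  v <- r$value[o]
  w <- (r$end - r$start)[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  lo <- v[which(cw >= half)[1]]
  hi <- v[which(cw > half)[1]]
  if (is.na(hi)) hi <- lo
  (lo + hi) / 2
}

#' Detect RNA pol II-occupied genes
#'
#' A gene is scored occupied in one replicate if, in the strand-oriented
#' promoter window `[TSS - window, TSS + window)`, either (peaks mode) at
#' least one peak overlaps the window, or (threshold mode) mean normalized
#' coverage is at least `theta` times the genome-wide width-weighted median
#' of nonzero coverage for that replicate. A gene is occupied overall if
#' scored occupied in at least `quorum` replicates (default: majority).
#' Occupancy is evaluated on WT samples only, so the universe does not
#' depend on the genotype effect under study.
#'
#' @param annotation a `genome_annotation`.
#' @param tracks list of normalized WT polII `coverage_track`s
#'   (threshold mode).
#' @param peaks list of peak data.frames (from [read_peaks()]), one per
#'   replicate (peaks mode).
#' @param mode `"threshold"` or `"peaks"`.
#' @param window promoter half-window around the TSS, bp.
#' @param theta threshold multiple of the median nonzero coverage.
#' @param quorum minimum number of supporting replicates; `NULL` = majority
#'   (`floor(n/2) + 1`).
#' @return Character vector of occupied gene ids.
#' @export
detect_occupied_genes <- function(annotation, tracks = NULL, peaks = NULL,
                                  mode = c("threshold", "peaks"),
                                  window = 1000, theta = 2, quorum = NULL) {
  mode <- match.arg(mode)
  g <- annotation$genes
  t0 <- tss(annotation)[g$gene_id]
  win_lo <- t0 - window
  win_hi <- t0 + window
  if (mode == "threshold") {
    if (is.null(tracks) || !length(tracks)) .stopf("threshold mode needs >= 1 coverage track")
    nrep <- length(tracks)
    votes <- matrix(FALSE, nrow(g), nrep)
    for (j in seq_len(nrep)) {
      tr <- tracks[[j]]
      med <- .median_nonzero_coverage(tr)
      means <- numeric(nrow(g))
      for (ch in unique(g$chrom)) {
        sel <- g$chrom == ch
        means[sel] <- .interval_means(tr, ch, win_lo[sel], win_hi[sel])
      }
      votes[, j] <- med > 0 & means >= theta * med
    }
  } else {
    if (is.null(peaks) || !length(peaks)) .stopf("peaks mode needs >= 1 peak set")
    nrep <- length(peaks)
    votes <- matrix(FALSE, nrow(g), nrep)
    for (j in seq_len(nrep)) {
      pk <- peaks[[j]]
      if (!nrow(pk)) {
        .warnf("empty peak set in replicate %d: contributes zero occupied genes", j)
        next
      }
      for (ch in unique(g$chrom)) {
        sel <- which(g$chrom == ch)
        p <- pk[pk$chrom == ch, , drop = FALSE]
        if (!nrow(p)) next
        # overlap of [win_lo, win_hi) with any peak [start, end)
        o <- order(p$start)
        ps <- p$start[o]; pe <- cummax(p$end[o])
        k <- findInterval(win_hi[sel] - 1e-9, ps)
        votes[sel, j] <- k > 0 & pe[pmax(k, 1)] > win_lo[sel]
      }
    }
  }
  if (is.null(quorum)) quorum <- floor(nrep / 2) + 1
  g$gene_id[rowSums(votes) >= quorum]
}

#' Apply the three universe filters
#'
#' Retains a gene iff it is occupied, strictly longer than `min_length`,
#' and its nearest other gene span on the same chromosome (either side,
#' strand-ignored) is at least `min_gap` bp away. Overlapping genes have
#' gap 0 and fail the gap test. Per-gene outcomes for all three filters are
#' recorded.
#'
#' @param annotation a `genome_annotation`.
#' @param occupied character vector of occupied gene ids.
#' @param min_length strict length cutoff, bp ("longer than").
#' @param min_gap inclusive neighbour-gap cutoff, bp ("at least ... apart").
#' @return An object of class `gene_universe`: list with `gene_ids`
#'   (retained, in annotation order), `outcomes` (per-gene logical columns
#'   `occupied`, `length_ok`, `gap_ok`, `retained`) and `n`.
#' @export
filter_gene_universe <- function(annotation, occupied,
                                 min_length = 2000, min_gap = 2000) {
  g <- annotation$genes
  occ <- g$gene_id %in% occupied
  len_ok <- (g$end - g$start) > min_length
  gap <- rep(Inf, nrow(g))
  for (ch in unique(g$chrom)) {
    sel <- which(g$chrom == ch)
    if (length(sel) < 2) next
    o <- sel[order(g$start[sel], g$end[sel])]
    s <- g$start[o]; e <- g$end[o]
    n <- length(o)
    # gap to predecessor: start minus max end among earlier genes
    prev_end <- c(-Inf, cummax(e)[-n])
    gap_prev <- pmax(s - prev_end, 0)
    # gap to successor: successor start minus this end (suffix-min of
    # "next start - end" over later genes, since an overlapping later gene
    # gives gap 0 anyway)
    gap_next <- rep(Inf, n)
    sufmin <- rev(cummin(rev(s)))               # min start over i..n
    gap_next[-n] <- pmax(sufmin[-1] - e[-n], 0)
    gap[o] <- pmin(gap_prev, gap_next)
  }
  gap_ok <- gap >= min_gap
  retained <- occ & len_ok & gap_ok
  outcomes <- data.frame(gene_id = g$gene_id, occupied = occ,
                         length_ok = len_ok, gap_ok = gap_ok,
                         neighbor_gap = gap, retained = retained,
                         stringsAsFactors = FALSE)
  structure(list(gene_ids = g$gene_id[retained], outcomes = outcomes,
                 n = sum(retained)),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  o <- x$outcomes
  cat(sprintf("gene_universe: %d of %d genes retained (occupied %d, length_ok %d, gap_ok %d)\n",
              x$n, nrow(o), sum(o$occupied), sum(o$length_ok), sum(o$gap_ok)))
  invisible(x)
}

#' Write per-gene filter outcomes as TSV
#' @param universe a `gene_universe`.
#' @param path output file.
#' @param header_lines optional comment lines.
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path, header_lines = character()) {
  .write_tsv(universe$outcomes, path, header_lines)
}
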