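# Scale-regions occupancy quantification. Each gene contributes one row:
# fixed-size upstream flank bins, the gene body resampled into a fixed
# number of equal-width bins (length-weighted means, exact for fractional
# bp), and fixed-size downstream flank bins. Minus-strand rows are reversed
# so column 1 is always 5'-most. Region summaries use windows anchored at
# the TSS and TES.

#' Scale-regions layout parameters
#'
#' @param upstream,downstream flank extent, bp.
#' @param flank_bin flank bin size, bp (must divide both flank extents).
#' @param body_bins number of equal-width gene-body bins.
#' @param tss_halfwidth,tes_halfwidth half-width of the TSS/TES summary
#'   windows, bp.
#' @param pseudocount pseudocount added inside log2 transforms.
#' @return An object of class `region_layout`.
#' @export
region_layout <- function(upstream = 2000, downstream = 2000, flank_bin = 50,
                          body_bins = 100, tss_halfwidth = 250,
                          tes_halfwidth = 250, pseudocount = 1.0) {
  for (v in c(upstream = upstream, downstream = downstream, flank_bin = flank_bin,
              body_bins = body_bins, tss_halfwidth = tss_halfwidth,
              tes_halfwidth = tes_halfwidth, pseudocount = pseudocount))
    if (!is.numeric(v) || v <= 0) .stopf("all layout parameters must be > 0")
  if (upstream %% flank_bin != 0 || downstream %% flank_bin != 0)
    .stopf("flank extents must be divisible by flank_bin")
  structure(list(upstream = upstream, downstream = downstream,
                 flank_bin = flank_bin, body_bins = as.integer(body_bins),
                 tss_halfwidth = tss_halfwidth, tes_halfwidth = tes_halfwidth,
                 pseudocount = pseudocount),
            class = "region_layout")
}

.layout_ncol <- function(layout) {
  with(layout, upstream / flank_bin + body_bins + downstream / flank_bin)
}

#' Build a scale-regions occupancy matrix
#'
#' @param track a (normalized) `coverage_track`.
#' @param annotation a `genome_annotation`.
#' @param universe a `gene_universe` or character vector of gene ids (row
#'   set and order).
#' @param layout a `region_layout`.
#' @param log2_transform if `TRUE`, values are `log2(x + pseudocount)`.
#' @param modality stored modality tag.
#' @return An object of class `occupancy_matrix` with components `values`
#'   (genes x bins), `sample_id`, `modality`, `layout`, `log2` flag.
#' @export
build_scaled_matrix <- function(track, annotation, universe, layout = region_layout(),
                                log2_transform = FALSE, modality = NA_character_) {
  ids <- if (inherits(universe, "gene_universe")) universe$gene_ids else as.character(universe)
  if (!length(ids)) .stopf("empty gene universe")
  g <- annotation$genes[match(ids, annotation$genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id))
    .stopf("universe gene(s) missing from annotation: %s",
           paste(ids[is.na(g$gene_id)], collapse = ", "))
  n_up <- layout$upstream / layout$flank_bin
  n_dn <- layout$downstream / layout$flank_bin
  nb <- layout$body_bins
  ncol_total <- n_up + nb + n_dn
  # genomic (unoriented) bin edges per gene: left flank | body | right flank
  rel_left <- seq(-layout$upstream, 0, by = layout$flank_bin)   # n_up + 1
  rel_right <- seq(0, layout$downstream, by = layout$flank_bin) # n_dn + 1
  body_frac <- seq(0, 1, length.out = nb + 1)
  lens <- g$end - g$start
  edges <- cbind(
    outer(g$start, rel_left[-(n_up + 1)], `+`),
    g$start + outer(lens, body_frac),
    outer(g$end, rel_right[-1], `+`))
  vals <- matrix(NA_real_, nrow(g), ncol_total)
  for (ch in unique(g$chrom)) {
    sel <- which(g$chrom == ch)
    r <- track$runs[track$runs$chrom == ch, , drop = FALSE]
    e <- edges[sel, , drop = FALSE]
    a <- matrix(.cum_area_at(r, as.vector(e)), nrow = length(sel))
    w <- e[, -1, drop = FALSE] - e[, -ncol(e), drop = FALSE]
    vals[sel, ] <- (a[, -1, drop = FALSE] - a[, -ncol(a), drop = FALSE]) / w
  }
  minus <- g$strand == "-"
  if (any(minus)) vals[minus, ] <- vals[minus, ncol_total:1, drop = FALSE]
  if (log2_transform) vals <- log2(vals + layout$pseudocount)
  rownames(vals) <- g$gene_id
  colnames(vals) <- c(sprintf("up%03d", seq_len(n_up)),
                      sprintf("body%03d", seq_len(nb)),
                      sprintf("down%03d", seq_len(n_dn)))
  structure(list(values = vals, sample_id = track$sample_id,
                 modality = modality, layout = layout, log2 = log2_transform),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix '%s' (%s): %d genes x %d bins%s\n",
              x$sample_id, x$modality, nrow(x$values), ncol(x$values),
              if (x$log2) ", log2-transformed" else ""))
  invisible(x)
}

#' Per-pair log2 fold-change matrix
#'
#' Cellwise `log2((null + delta) / (WT + delta))` between two occupancy
#' matrices on the linear scale.
#'
#' @param null_matrix,wt_matrix `occupancy_matrix` objects sharing universe
#'   and layout, not log2-transformed.
#' @param delta pseudocount; defaults to the layout's.
#' @param pair_id stored pair identifier.
#' @return An object of class `fold_change_matrix`.
#' @export
pairwise_log2fc <- function(null_matrix, wt_matrix, delta = NULL, pair_id = NA_character_) {
  if (isTRUE(null_matrix$log2) || isTRUE(wt_matrix$log2))
    .stopf("fold changes are computed on the linear scale, not log2-transformed matrices")
  if (!identical(dim(null_matrix$values), dim(wt_matrix$values)) ||
      !identical(rownames(null_matrix$values), rownames(wt_matrix$values)))
    .stopf("matrix shape/universe mismatch between null and WT")
  if (is.null(delta)) delta <- null_matrix$layout$pseudocount
  .check_scalar_num(delta, "delta", positive = TRUE)
  fc <- log2((null_matrix$values + delta) / (wt_matrix$values + delta))
  structure(list(values = fc, pair_id = pair_id,
                 modality = null_matrix$modality, layout = null_matrix$layout,
                 delta = delta),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf("fold_change_matrix pair '%s' (%s): %d genes x %d bins, delta=%g\n",
              x$pair_id, x$modality, nrow(x$values), ncol(x$values), x$delta))
  invisible(x)
}

#' Region summaries per gene
#'
#' Strand-oriented window means of coverage: TSS window
#' `[TSS - h, TSS + h)`, gene body between (and excluding) the TSS and TES
#' windows, TES window `[TES - h, TES + h)`, and the upstream/downstream
#' flank windows of the layout.
#'
#' @param track a (normalized) `coverage_track`.
#' @param annotation a `genome_annotation`.
#' @param universe a `gene_universe` or character vector of gene ids.
#' @param layout a `region_layout`.
#' @return data.frame: `gene_id`, `tss`, `body`, `tes`, `upstream`,
#'   `downstream`.
#' @export
summarize_regions <- function(track, annotation, universe, layout = region_layout()) {
  ids <- if (inherits(universe, "gene_universe")) universe$gene_ids else as.character(universe)
  if (!length(ids)) .stopf("empty gene universe")
  g <- annotation$genes[match(ids, annotation$genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) .stopf("universe gene(s) missing from annotation")
  ht <- layout$tss_halfwidth
  he <- layout$tes_halfwidth
  plus <- g$strand == "+"
  t0 <- ifelse(plus, g$start, g$end)   # TSS
  t1 <- ifelse(plus, g$end, g$start)   # TES
  # body between the windows, in genomic coordinates
  body_lo <- ifelse(plus, t0 + ht, t1 + he)
  body_hi <- ifelse(plus, t1 - he, t0 - ht)
  bad <- body_hi <= body_lo
  if (any(bad))
    .stopf("TSS/TES windows collide (empty body) for gene(s): %s",
           paste(g$gene_id[bad], collapse = ", "))
  up_lo <- ifelse(plus, t0 - layout$upstream, t0)
  up_hi <- ifelse(plus, t0, t0 + layout$upstream)
  dn_lo <- ifelse(plus, t1, t1 - layout$downstream)
  dn_hi <- ifelse(plus, t1 + layout$downstream, t1)
  out <- data.frame(gene_id = g$gene_id, tss = NA_real_, body = NA_real_,
                    tes = NA_real_, upstream = NA_real_, downstream = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(g$chrom)) {
    sel <- which(g$chrom == ch)
    out$tss[sel] <- .interval_means(track, ch, t0[sel] - ht, t0[sel] + ht)
    out$body[sel] <- .interval_means(track, ch, body_lo[sel], body_hi[sel])
    out$tes[sel] <- .interval_means(track, ch, t1[sel] - he, t1[sel] + he)
    out$upstream[sel] <- .interval_means(track, ch, up_lo[sel], up_hi[sel])
    out$downstream[sel] <- .interval_means(track, ch, dn_lo[sel], dn_hi[sel])
  }
  out
}

#' Metagene profile (column means)
#'
#' @param matrix an `occupancy_matrix` or `fold_change_matrix`.
#' @param genes optional gene-id subset (e.g. one cluster).
#' @return List with `profile` (per-bin mean vector) and `n_genes`.
#' @export
metagene_profile <- function(matrix, genes = NULL) {
  v <- matrix$values
  if (!is.null(genes)) {
    idx <- match(genes, rownames(v))
    if (anyNA(idx)) .stopf("gene(s) not in matrix: %s",
                           paste(genes[is.na(idx)], collapse = ", "))
    v <- v[idx, , drop = FALSE]
  }
  if (!nrow(v)) .stopf("empty gene selection")
  list(profile = colMeans(v), n_genes = nrow(v))
}

#' Write an occupancy or fold-change matrix as TSV
#'
#' The header comment line encodes the layout so row/column semantics
#' travel with the file.
#'
#' @param m an `occupancy_matrix` or `fold_change_matrix`.
#' @param path output file.
#' @param header_lines extra comment lines.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, header_lines = character()) {
  lay <- m$layout
  hdr <- c(sprintf("layout upstream=%g downstream=%g flank_bin=%g body_bins=%d tss_halfwidth=%g tes_halfwidth=%g pseudocount=%g",
                   lay$upstream, lay$downstream, lay$flank_bin, lay$body_bins,
                   lay$tss_halfwidth, lay$tes_halfwidth, lay$pseudocount),
           header_lines)
  df <- data.frame(gene_id = rownames(m$values), m$values, check.names = FALSE)
  .write_tsv(df, path, hdr)
}

#' Plot a metagene profile
#'
#' Base-graphics line plot of per-bin means, with flank/body boundaries
#' marked.
#'
#' @param matrix an `occupancy_matrix` or `fold_change_matrix`.
#' @param genes optional gene subset.
#' @param ... passed to [graphics::plot()].
#' @return The profile list, invisibly.
#' @export
plot_metagene <- function(matrix, genes = NULL, ...) {
  p <- metagene_profile(matrix, genes)
  lay <- matrix$layout
  n_up <- lay$upstream / lay$flank_bin
  nb <- lay$body_bins
  graphics::plot(seq_along(p$profile), p$profile, type = "l",
                 xlab = "bin (5' flank | scaled body | 3' flank)",
                 ylab = "mean value", ...)
  graphics::abline(v = c(n_up + 0.5, n_up + nb + 0.5), lty = 2, col = "grey50")
  invisible(p)
}
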