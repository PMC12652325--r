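# Run-length coverage container and bedGraph I/O.
#
# A coverage_track stores per-chromosome coverage as sorted, non-overlapping
# runs (start, end, value) with gaps implicitly zero. Tracks are canonical:
# zero-value runs are dropped and adjacent runs with equal value are merged,
# so bedGraph round-trips are byte-stable.

.canonicalize_runs <- function(runs) {
  runs <- runs[runs$value != 0, , drop = FALSE]
  if (!nrow(runs)) {
    rownames(runs) <- NULL
    return(runs)
  }
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  # merge adjacent equal-value runs within a chromosome
  same <- c(FALSE, runs$chrom[-1] == runs$chrom[-nrow(runs)] &
                   runs$start[-1] == runs$end[-nrow(runs)] &
                   runs$value[-1] == runs$value[-nrow(runs)])
  grp <- cumsum(!same)
  if (any(same)) {
    runs <- data.frame(
      chrom = runs$chrom[!same],
      start = runs$start[!same],
      end = tapply(runs$end, grp, function(e) e[length(e)])[as.character(unique(grp))],
      value = runs$value[!same],
      stringsAsFactors = FALSE)
  }
  rownames(runs) <- NULL
  runs
}

#' Construct a coverage track
#'
#' @param runs data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals, non-negative values). Overlapping
#'   intervals are rejected; gaps are implicitly zero.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param sample_id sample identifier.
#' @param namespace `"target"` or `"spikein"`.
#' @param total_fragments fragment count behind the track, or `NA` if
#'   unknown (it can then be estimated from coverage area).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(runs, chrom_sizes, sample_id = "sample",
                           namespace = "target", total_fragments = NA_real_) {
  namespace <- match.arg(namespace, c("target", "spikein"))
  req <- c("chrom", "start", "end", "value")
  miss <- setdiff(req, names(runs))
  if (length(miss)) .stopf("runs is missing column(s): %s", paste(miss, collapse = ", "))
  runs <- as.data.frame(runs)[req]
  runs$chrom <- as.character(runs$chrom)
  runs$start <- as.numeric(runs$start)
  runs$end <- as.numeric(runs$end)
  runs$value <- as.numeric(runs$value)
  if (any(runs$end <= runs$start))
    .stopf("interval with end <= start in coverage runs")
  if (any(runs$value < 0) || any(!is.finite(runs$value)))
    .stopf("coverage values must be finite and >= 0")
  if (is.null(names(chrom_sizes))) .stopf("chrom_sizes must be a named vector")
  absent <- setdiff(unique(runs$chrom), names(chrom_sizes))
  if (length(absent))
    .stopf("chromosome(s) not in chrom_sizes: %s", paste(absent, collapse = ", "))
  if (any(runs$start < 0 | runs$end > chrom_sizes[runs$chrom]))
    .stopf("interval beyond chromosome bounds")
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  if (nrow(runs) > 1) {
    ovl <- runs$chrom[-1] == runs$chrom[-nrow(runs)] &
           runs$start[-1] < runs$end[-nrow(runs)]
    if (any(ovl)) .stopf("overlapping intervals in coverage runs (chrom %s at %g)",
                         runs$chrom[-1][ovl][1], runs$start[-1][ovl][1])
  }
  runs <- .canonicalize_runs(runs)
  structure(list(sample_id = sample_id, namespace = namespace,
                 runs = runs, chrom_sizes = chrom_sizes,
                 total_fragments = as.numeric(total_fragments)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s' [%s]: %d runs, area %.4g, fragments %s\n",
              x$sample_id, x$namespace, nrow(x$runs), coverage_area(x),
              if (is.na(x$total_fragments)) "NA" else format(x$total_fragments)))
  invisible(x)
}

#' Total coverage area (sum of value x width)
#' @param track a `coverage_track`.
#' @return A single number.
#' @export
coverage_area <- function(track) {
  with(track$runs, sum(value * (end - start)))
}

#' Read a 4-column bedGraph into a coverage track
#'
#' @param path bedGraph file (chrom, start, end, value; tab or space
#'   separated; `track`/`#` lines ignored).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param namespace `"target"` or `"spikein"`.
#' @param sample_id sample identifier (defaults to the file name).
#' @param total_fragments known fragment count, or `NA`.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_sizes, namespace = "target",
                          sample_id = sub("\\.[^.]*$", "", basename(path)),
                          total_fragments = NA_real_) {
  if (!file.exists(path)) .stopf("bedGraph file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    runs <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), value = numeric())
    tf <- if (is.na(total_fragments)) 0 else total_fragments
    return(coverage_track(runs, chrom_sizes, sample_id, namespace, tf))
  }
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  bad <- which(n < 4)
  if (length(bad))
    .stopf("parse error at line %d of %s: bedGraph needs 4 columns", lineno[bad[1]], path)
  runs <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(runs$start) | is.na(runs$end) | is.na(runs$value))
  if (length(bad))
    .stopf("parse error at line %d of %s: non-numeric field", lineno[bad[1]], path)
  if (any(runs$value < 0))
    .stopf("negative coverage value at line %d of %s",
           lineno[which(runs$value < 0)[1]], path)
  coverage_track(runs, chrom_sizes, sample_id, namespace, total_fragments)
}

#' Write a coverage track as bedGraph
#'
#' Only nonzero runs are written (gaps are implicitly zero), in the track's
#' canonical run-length form, so `read_bedgraph(write_bedgraph(x))`
#' reproduces `x$runs` exactly.
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- track$runs
  lines <- sprintf("%s\t%s\t%s\t%s", r$chrom,
                   format(r$start, scientific = FALSE, trim = TRUE),
                   format(r$end, scientific = FALSE, trim = TRUE),
                   format(r$value, digits = 17, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Scale a coverage track by a positive factor
#'
#' @param track a `coverage_track`.
#' @param factor positive scale factor.
#' @return A `coverage_track` with every value multiplied by `factor`.
#' @export
normalize_track <- function(track, factor) {
  .check_scalar_num(factor, "factor", positive = TRUE)
  track$runs$value <- track$runs$value * factor
  track
}

# Piecewise-linear cumulative-area evaluation: for query positions `x` on one
# chromosome, returns integral of coverage over [0, x). Vectorized; positions
# outside [0, chrom length] are clamped (coverage is zero there).
.cum_area_at <- function(runs, x) {
  x <- pmax(x, 0)
  if (!nrow(runs)) return(numeric(length(x)))
  w <- runs$end - runs$start
  cum0 <- c(0, cumsum(runs$value * w))[seq_len(nrow(runs))]
  k <- findInterval(x, runs$start)
  out <- numeric(length(x))
  nz <- k > 0
  kk <- k[nz]
  out[nz] <- cum0[kk] + runs$value[kk] * pmin(pmax(x[nz] - runs$start[kk], 0), w[kk])
  out
}

# Mean coverage over arbitrary intervals [from, to) on chromosome `chrom`
# (vectorized over intervals; all on the same chromosome).
.interval_means <- function(track, chrom, from, to) {
  r <- track$runs[track$runs$chrom == chrom, , drop = FALSE]
  (.cum_area_at(r, to) - .cum_area_at(r, from)) / (to - from)
}

# Build disjoint runs from possibly-overlapping weighted intervals by event
# sweeping (values add where intervals overlap).
.runs_from_intervals <- function(chrom, start, end, value) {
  keep <- value != 0 & end > start
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]; value <- value[keep]
  if (!length(start))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  out <- lapply(split(seq_along(start), chrom), function(idx) {
    pos <- c(start[idx], end[idx])
    dv <- c(value[idx], -value[idx])
    o <- order(pos)
    pos <- pos[o]; dv <- dv[o]
    # collapse equal positions
    grp <- cumsum(!duplicated(pos))
    upos <- pos[!duplicated(pos)]
    ulev <- cumsum(vapply(split(dv, grp), sum, 0))
    n <- length(upos)
    data.frame(chrom = chrom[idx][1], start = upos[-n], end = upos[-1],
               value = ulev[-n], stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, out)
  # float dust from the event sweep: values are sums/differences of many
  # positive terms, so anything within ~1e-9 relative of zero is zero
  tol <- 1e-9 * max(abs(runs$value), 1)
  runs$value[abs(runs$value) < tol] <- 0
  runs$value <- pmax(runs$value, 0)
  .canonicalize_runs(runs)
}
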