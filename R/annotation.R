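# Gene annotation container and readers.
#
# A genome_annotation holds one gene model per row (gene_id, chrom, start,
# end, strand) in 0-based half-open coordinates, plus chromosome sizes and a
# namespace tag separating the target genome from the exogenous spike-in
# genome. TSS/TES are strand-resolved: TSS = start on "+", end on "-".

#' Construct a genome annotation
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` ("+"/"-"); coordinates 0-based half-open.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param namespace `"target"` or `"spikein"`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, chrom_sizes, namespace = "target") {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) .stopf("genes is missing column(s): %s", paste(miss, collapse = ", "))
  genes <- as.data.frame(genes)[req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  namespace <- match.arg(namespace, c("target", "spikein"))
  if (anyDuplicated(genes$gene_id))
    .stopf("duplicate gene_id: %s",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    .stopf("strand must be '+' or '-'")
  if (any(genes$end <= genes$start))
    .stopf("gene(s) with end <= start: %s",
           paste(genes$gene_id[genes$end <= genes$start], collapse = ", "))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    .stopf("chrom_sizes must be a named vector")
  absent <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(absent))
    .stopf("chromosome(s) not in chrom_sizes: %s", paste(absent, collapse = ", "))
  bad <- genes$start < 0 | genes$end > chrom_sizes[genes$chrom]
  if (any(bad))
    .stopf("gene(s) extend past chromosome bounds: %s",
           paste(genes$gene_id[bad], collapse = ", "))
  rownames(genes) <- NULL
  structure(list(genes = genes, chrom_sizes = chrom_sizes, namespace = namespace),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation [%s]: %d genes on %d chromosome(s)\n",
              x$namespace, nrow(x$genes), length(x$chrom_sizes)))
  invisible(x)
}

#' Strand-resolved transcription start / end sites
#'
#' @param annotation a `genome_annotation`.
#' @return Named numeric vector (gene_id -> coordinate).
#' @export
tss <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$start, g$end), g$gene_id)
}

#' @rdname tss
#' @export
tes <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$end, g$start), g$gene_id)
}

#' Gene lengths in bp
#' @param annotation a `genome_annotation`.
#' @return Named numeric vector.
#' @export
gene_lengths <- function(annotation) {
  g <- annotation$genes
  stats::setNames(g$end - g$start, g$gene_id)
}

.read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("chrom sizes file '%s' needs 2 columns", path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a gene annotation from BED or minimal GTF
#'
#' BED input (6 or 12 columns) is taken as-is (0-based half-open); GTF input
#' (only `gene` feature lines are used) is converted from 1-based inclusive.
#' Duplicate gene identifiers and out-of-bounds genes are rejected.
#'
#' @param path annotation file.
#' @param chrom_sizes named numeric vector, or path to a two-column
#'   `<chrom>\t<length>` file.
#' @param format `"bed"` or `"gtf"`; default guesses from the extension.
#' @param namespace `"target"` or `"spikein"`.
#' @return A `genome_annotation`.
#' @export
read_gene_annotation <- function(path, chrom_sizes, format = c("auto", "bed", "gtf"),
                                 namespace = "target") {
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- .read_chrom_sizes(chrom_sizes)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) .stopf("no gene records in %s", path)
  fields <- strsplit(lines, "\t")
  if (format == "bed") {
    n <- lengths(fields)
    bad <- which(n < 6)
    if (length(bad))
      .stopf("parse error at line %d of %s: BED needs >= 6 columns", lineno[bad[1]], path)
    genes <- data.frame(
      gene_id = vapply(fields, `[[`, "", 4L),
      chrom = vapply(fields, `[[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
      end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
      strand = vapply(fields, `[[`, "", 6L),
      stringsAsFactors = FALSE)
  } else {
    n <- lengths(fields)
    bad <- which(n < 9)
    if (length(bad))
      .stopf("parse error at line %d of %s: GTF needs 9 columns", lineno[bad[1]], path)
    feat <- vapply(fields, `[[`, "", 3L)
    sel <- feat == "gene"
    if (!any(sel)) .stopf("no 'gene' feature lines in %s", path)
    fields <- fields[sel]
    attrs <- vapply(fields, `[[`, "", 9L)
    m <- regmatches(attrs, regexpr('gene_id[ =]+"?[^";]+"?', attrs))
    if (length(m) != length(attrs))
      .stopf("gene line without gene_id attribute in %s", path)
    ids <- gsub('^gene_id[ =]+"?|"$', "", m)
    genes <- data.frame(
      gene_id = ids,
      chrom = vapply(fields, `[[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))) - 1,
      end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))),
      strand = vapply(fields, `[[`, "", 7L),
      stringsAsFactors = FALSE)
  }
  bad <- which(is.na(genes$start) | is.na(genes$end))
  if (length(bad))
    .stopf("parse error at line %d of %s: non-numeric coordinate",
           if (format == "bed") lineno[bad[1]] else bad[1], path)
  genome_annotation(genes, chrom_sizes, namespace)
}

#' Write an annotation as BED12
#'
#' Single-block BED12 records (one exon spanning the gene).
#'
#' @param annotation a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(annotation, path) {
  g <- annotation$genes
  df <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                   g$start, g$end, "0,0,0", 1L, g$end - g$start, 0L)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(names(chrom_sizes), format(chrom_sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
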