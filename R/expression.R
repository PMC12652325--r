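# RNA-seq expression container: raw gene counts with library sizes and
# reads-per-million normalization.

#' Construct an expression table
#'
#' @param counts genes x samples matrix of non-negative integer counts with
#'   row names (gene ids) and column names (sample ids).
#' @param genotype character vector, one of WT/null per column of `counts`.
#' @return An object of class `expression_table` with components `counts`,
#'   `genotype`, `lib_size` (column sums) and `rpm`
#'   (counts / lib_size * 1e6).
#' @export
expression_table <- function(counts, genotype) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must have gene row names and sample column names")
  if (any(counts < 0) || any(counts != round(counts)))
    .stopf("counts must be non-negative integers")
  if (length(genotype) != ncol(counts))
    .stopf("genotype must have one entry per sample column")
  bad <- setdiff(unique(genotype), .genotypes)
  if (length(bad)) .stopf("unknown genotype value(s): %s", paste(bad, collapse = ", "))
  lib <- colSums(counts)
  rpm <- sweep(counts, 2, ifelse(lib > 0, lib, 1), "/") * 1e6
  structure(list(counts = counts, genotype = as.character(genotype),
                 lib_size = lib, rpm = rpm),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", .genotypes, table(factor(x$genotype, .genotypes))),
                    collapse = ", ")))
  invisible(x)
}

#' Read an RNA-seq count TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Genotypes are taken from `sheet` (matching on sample id) or from a
#' `genotype` argument.
#'
#' @param path counts TSV.
#' @param sheet optional `sample_sheet` carrying genotypes for the RNA
#'   samples.
#' @param genotype optional explicit genotype vector (overrides `sheet`).
#' @return An `expression_table`.
#' @export
read_expression_counts <- function(path, sheet = NULL, genotype = NULL) {
  if (!file.exists(path)) .stopf("counts file not found: %s", path)
  df <- .read_tsv(path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  if (is.null(genotype)) {
    if (is.null(sheet)) .stopf("supply either a sample sheet or a genotype vector")
    idx <- match(colnames(counts), sheet$sample_id)
    if (anyNA(idx))
      .stopf("count column(s) not in sample sheet: %s",
             paste(colnames(counts)[is.na(idx)], collapse = ", "))
    genotype <- sheet$genotype[idx]
  }
  expression_table(counts, genotype)
}

#' Write expression counts as TSV
#' @param expr an `expression_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_counts <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene mean RPM by genotype
#' @param expr an `expression_table`.
#' @return A data.frame with columns `gene_id`, `WT`, `null`.
#' @export
genotype_mean_rpm <- function(expr) {
  wt <- rowMeans(expr$rpm[, expr$genotype == "WT", drop = FALSE])
  nl <- rowMeans(expr$rpm[, expr$genotype == "null", drop = FALSE])
  data.frame(gene_id = rownames(expr$counts), WT = wt, null = nl,
             row.names = NULL, stringsAsFactors = FALSE)
}
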