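#' @keywords internal
"_PACKAGE"

# Shared internal helpers. All coordinates in the package are 0-based,
# half-open (BED convention); GTF input is converted on read.

.modalities_chip <- c("AFF4", "polII", "pS2polII")
.modalities_all <- c(.modalities_chip, "RNA")
.genotypes <- c("WT", "null")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)

.check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    .stopf("'%s' must be > 0 (got %g)", name, x)
  invisible(x)
}

# Deterministic RNG scope: evaluates `expr` under a fixed seed and restores
# the caller's RNG state afterwards, so generator calls never perturb (and are
# never perturbed by) ambient randomness.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .stopf("label vectors differ in length")
  if (length(a) < 2) .stopf("need at least 2 items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# write a data.frame as TSV with optional "#"-prefixed header lines
.write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
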