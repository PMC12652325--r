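# Sample sheet: one row per sequencing sample. ChIP modalities come in
# matched animal pairs (one WT + one null per pair_id and modality) with a
# target and a spike-in coverage file each; RNA samples are unpaired
# replicates without spike-in.

#' Read and validate a TSV sample sheet
#'
#' Required columns: `sample_id`, `genotype` (WT/null), `modality`
#' (AFF4/polII/pS2polII/RNA), `pair_id` (empty for RNA), `target_path`,
#' `spikein_path` (empty for RNA). Optional columns `target_fragments` and
#' `spikein_fragments` carry known fragment counts (preferred over
#' area-based estimation). The matched-pair invariant — exactly one WT and
#' one null sample per (pair_id, modality) — is checked across the sheet.
#'
#' @param path TSV file with a header.
#' @param base_dir directory against which relative file paths are resolved;
#'   defaults to the sheet's directory.
#' @return A data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) .stopf("sample sheet not found: %s", path)
  df <- .read_tsv(path, colClasses = "character")
  validate_sample_sheet(df, base_dir = base_dir)
}

#' @rdname read_sample_sheet
#' @param df a data.frame with the sample-sheet columns (in-memory variant).
#' @export
validate_sample_sheet <- function(df, base_dir = NULL) {
  req <- c("sample_id", "genotype", "modality", "pair_id", "target_path", "spikein_path")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    .stopf("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(df$genotype), .genotypes)
  if (length(bad)) .stopf("unknown genotype value(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$modality), .modalities_all)
  if (length(bad)) .stopf("unknown modality value(s): %s (expected %s)",
                          paste(bad, collapse = ", "), paste(.modalities_all, collapse = "/"))
  for (col in c("target_fragments", "spikein_fragments"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]]) else df[[col]] <- NA_real_
  if (!is.null(base_dir))
    for (col in c("target_path", "spikein_path")) {
      rel <- nzchar(df[[col]]) & !grepl("^/", df[[col]])
      df[[col]][rel] <- file.path(base_dir, df[[col]][rel])
    }
  chip <- df[df$modality != "RNA", , drop = FALSE]
  if (nrow(chip)) {
    if (any(!nzchar(chip$pair_id)))
      .stopf("ChIP sample(s) without pair_id: %s",
             paste(chip$sample_id[!nzchar(chip$pair_id)], collapse = ", "))
    for (key in unique(paste(chip$pair_id, chip$modality))) {
      sel <- paste(chip$pair_id, chip$modality) == key
      gts <- sort(chip$genotype[sel])
      if (!identical(gts, sort(.genotypes)))
        .stopf("pairing error for (pair_id modality) = (%s): need exactly one WT and one null, got {%s}",
               key, paste(chip$genotype[sel], collapse = ", "))
    }
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet TSV
#' @param sheet a `sample_sheet` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  df <- as.data.frame(sheet)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a sample sheet by modality
#' @param sheet a `sample_sheet`.
#' @return Named list of data.frames, one per modality present.
#' @export
samples_by_modality <- function(sheet) {
  split(as.data.frame(sheet), sheet$modality)
}
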