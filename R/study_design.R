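#' Build a study design from per-sample records
#'
#' A study design records, for every sample, its control class and — for
#' positive controls — the known input (cells for extraction controls, genome
#' copies for PCR controls) and the expected target organism.
#'
#' @param records A data frame with columns `sample_id`, `control_class`
#'   (one of `extraction_positive`, `pcr_positive`, `extraction_negative`,
#'   `pcr_negative`, `blank`, `sample`) and optionally `input_cells`,
#'   `target_spec`, `plate`, `well`.
#' @return A tibble of class `katharo_design` with one validated row per
#'   sample.
#' @details Positive-control rows must carry a positive `input_cells`;
#'   other classes may leave it missing (or 0, which is treated as missing).
#'   `target_spec` is a lineage substring (e.g. `"g__Bacillus"`) matched
#'   case-insensitively against the feature table's taxonomy.
#' @export
study_design <- function(records) {
  records <- as_tibble(records)
  if (!all(c("sample_id", "control_class") %in% names(records))) {
    ks_abort("Metadata needs `sample_id` and `control_class` columns.",
             "malformed_header")
  }
  if (anyDuplicated(records$sample_id)) {
    ks_abort("Duplicate sample ids in metadata.", "duplicate_ids")
  }
  bad <- setdiff(unique(records$control_class), CONTROL_CLASSES)
  if (length(bad)) {
    ks_abort(paste0("Unknown control_class token(s): ",
                    paste(bad, collapse = ", "), ". Expected one of: ",
                    paste(CONTROL_CLASSES, collapse = ", "), "."),
             "unknown_class")
  }
  for (col in c("input_cells", "target_spec", "plate", "well")) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "input_cells") NA_real_ else NA_character_
    }
  }
  records$input_cells <- suppressWarnings(as.numeric(records$input_cells))
  records$input_cells[!is.na(records$input_cells) & records$input_cells == 0] <- NA_real_
  pos <- records$control_class %in% POSITIVE_CLASSES
  if (any(pos & is.na(records$input_cells))) {
    ks_abort("Positive-control rows must state `input_cells` (> 0).",
             "missing_input_cells")
  }
  if (any(pos & records$input_cells <= 0, na.rm = TRUE)) {
    ks_abort("`input_cells` must be positive.", "missing_input_cells")
  }
  if (any(!pos & !is.na(records$input_cells))) {
    ks_abort("`input_cells` is only meaningful for positive-control rows.",
             "invalid_input_cells")
  }
  records <- records[, c("sample_id", "control_class", "input_cells",
                         "target_spec", "plate", "well")]
  class(records) <- unique(c("katharo_design", class(records)))
  records
}

#' Read a sample metadata table
#'
#' Tab-separated, QIIME-style: a `#SampleID` header is accepted as an alias
#' for `sample_id`.
#'
#' @param path Path to the TSV metadata file.
#' @return A `katharo_design` tibble; see [study_design()].
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    ks_abort(paste0("No such file: ", path), "missing_file")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  names(df)[names(df) %in% c("#SampleID", "#sample_id", "sampleid", "SampleID")] <- "sample_id"
  study_design(df)
}

#' Write a study design to a TSV sample map
#' @param design A `katharo_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(design, path) {
  stopifnot(inherits(design, "katharo_design"))
  readr::write_tsv(as_tibble(design), path, na = "", progress = FALSE)
  invisible(path)
}

#' Titration levels of a study design
#'
#' @param design A `katharo_design`.
#' @param classes Positive-control classes to consider.
#' @return Sorted distinct `input_cells` values among the selected positive
#'   controls; `numeric(0)` when there are none.
#' @export
titration_levels <- function(design, classes = POSITIVE_CLASSES) {
  stopifnot(inherits(design, "katharo_design"))
  lv <- design$input_cells[design$control_class %in% classes]
  sort(unique(lv[!is.na(lv)]))
}
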