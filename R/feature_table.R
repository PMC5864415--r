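#' Construct a feature count table
#'
#' A `feature_table` holds non-negative integer counts of features (sOTUs,
#' ASVs, taxa) per sample, as a features-by-samples matrix, with an optional
#' taxonomy annotation (semicolon-delimited lineage string) per feature.
#'
#' @param counts Numeric matrix, features in rows and samples in columns, with
#'   unique row and column names. All values must be non-negative whole
#'   numbers; fractional counts are rejected rather than rounded so that
#'   read-depth semantics stay exact.
#' @param taxonomy Optional named character vector mapping feature ids (a
#'   subset of `rownames(counts)`) to lineage strings.
#'
#' @return An object of class `feature_table`.
#' @examples
#' m <- matrix(c(906L, 0L, 94L, 10L), nrow = 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' feature_table(m, taxonomy = c(f1 = "k__Bacteria;g__Bacillus;s__subtilis"))
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    ks_abort("`counts` must have feature ids as row names.", "malformed_header")
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    ks_abort("`counts` must have sample ids as column names.", "malformed_header")
  }
  if (anyDuplicated(rownames(counts))) {
    ks_abort("Duplicate feature ids in count table.", "duplicate_ids")
  }
  if (anyDuplicated(colnames(counts))) {
    ks_abort("Duplicate sample ids in count table.", "duplicate_ids")
  }
  if (length(counts) && (!is.numeric(counts) || anyNA(counts))) {
    ks_abort("Counts must be numeric and non-missing.", "nonnumeric_counts")
  }
  if (length(counts) && any(counts < 0)) {
    ks_abort("Counts must be non-negative.", "negative_counts")
  }
  if (length(counts) && any(counts != round(counts))) {
    ks_abort("Counts must be whole numbers; fractional counts are rejected, not rounded.",
             "fractional_counts")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !is.character(taxonomy)) {
      ks_abort("`taxonomy` must be a named character vector.", "invalid_taxonomy")
    }
    taxonomy <- taxonomy[!is.na(taxonomy)]
    unknown <- setdiff(names(taxonomy), rownames(counts))
    if (length(unknown)) {
      ks_abort(paste0("Taxonomy given for unknown feature ids: ",
                      paste(head(unknown, 3), collapse = ", ")),
               "invalid_taxonomy")
    }
    if (length(taxonomy) == 0) taxonomy <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("  taxonomy for %d features\n", length(x$taxonomy)))
  }
  if (ncol(x$counts)) {
    cat("  samples:", paste(head(colnames(x$counts), 5), collapse = ", "),
        if (ncol(x$counts) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Sample and feature identifiers of a feature table
#' @param table A [feature_table()].
#' @return Character vector of ids, in table order.
#' @export
sample_ids <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  colnames(table$counts) %||% character(0)
}

#' @rdname sample_ids
#' @export
feature_ids <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rownames(table$counts) %||% character(0)
}

#' Tidy view of a feature table
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with one row per feature/sample pair: `feature_id`,
#'   `sample_id`, `count`, and `taxonomy` when the table is annotated.
#' @export
as_tibble.feature_table <- function(x, ...) {
  out <- tibble(
    feature_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  if (!is.null(x$taxonomy)) {
    out$taxonomy <- unname(x$taxonomy[out$feature_id])
  }
  out
}

#' Read a feature table from TSV or BIOM
#'
#' The TSV dialect is features as rows and samples as columns: first column
#' the feature id, one column per sample, and an optional final `taxonomy`
#' column. BIOM files (JSON or HDF5) are read through the biomformat package,
#' taking the first observation-metadata field as the lineage string.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ks_abort(paste0("No such file: ", path), "missing_file")
  }
  if (format == "biom") {
    return(read_feature_table_biom(path))
  }
  df <- as.data.frame(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  if (ncol(df) < 1 || is.na(names(df)[1]) || names(df)[1] == "") {
    ks_abort("Malformed header: need a feature-id column.", "malformed_header")
  }
  tax_col <- which(tolower(names(df)) == "taxonomy")
  if (length(tax_col) > 1) {
    ks_abort("Malformed header: multiple taxonomy columns.", "malformed_header")
  }
  sample_cols <- setdiff(seq_len(ncol(df))[-1], tax_col)
  if (anyDuplicated(names(df)[sample_cols])) {
    ks_abort("Duplicate sample ids in header.", "duplicate_ids")
  }
  feature_id <- df[[1]]
  if (anyDuplicated(feature_id)) {
    ks_abort("Duplicate feature ids.", "duplicate_ids")
  }
  counts <- matrix(0L, nrow = nrow(df), ncol = length(sample_cols),
                   dimnames = list(feature_id, names(df)[sample_cols]))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(df[[sample_cols[j]]]))
    if (anyNA(v)) {
      ks_abort(paste0("Non-numeric count in sample column '",
                      names(df)[sample_cols[j]], "'."), "nonnumeric_counts")
    }
    counts[, j] <- v
  }
  taxonomy <- NULL
  if (length(tax_col) == 1) {
    tx <- df[[tax_col]]
    keep <- !is.na(tx) & tx != ""
    if (any(keep)) taxonomy <- setNames(tx[keep], feature_id[keep])
  }
  feature_table(counts, taxonomy = taxonomy)
}

read_feature_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    ks_abort("Reading BIOM requires the biomformat package.", "missing_dependency")
  }
  b <- biomformat::read_biom(path)
  counts <- as(biomformat::biom_data(b), "matrix")
  taxonomy <- NULL
  om <- tryCatch(suppressWarnings(biomformat::observation_metadata(b)),
                 error = function(e) NULL)
  if (!is.null(om)) {
    lineage <- if (is.data.frame(om)) {
      apply(om, 1, function(r) paste(r[!is.na(r) & r != ""], collapse = "; "))
    } else if (is.list(om)) {
      vapply(om, function(r) paste(unlist(r), collapse = "; "), character(1))
    } else {
      NULL
    }
    if (!is.null(lineage)) {
      lineage <- lineage[lineage != ""]
      if (length(lineage)) taxonomy <- lineage[names(lineage) %in% rownames(counts)]
      if (length(taxonomy) == 0) taxonomy <- NULL
    }
  }
  feature_table(counts, taxonomy = taxonomy)
}

#' Write a feature table to TSV or BIOM
#'
#' TSV output is canonical and byte-stable for a fixed table: features in
#' table order, samples in table order, taxonomy (when present) as the last
#' column. BIOM output goes through biomformat.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "feature_table"))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      ks_abort("Writing BIOM requires the biomformat package.", "missing_dependency")
    }
    om <- NULL
    if (!is.null(table$taxonomy)) {
      tx <- table$taxonomy[rownames(table$counts)]
      tx[is.na(tx)] <- ""
      om <- data.frame(taxonomy = unname(tx), row.names = rownames(table$counts))
    }
    b <- biomformat::make_biom(table$counts, observation_metadata = om)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- as.data.frame(table$counts, check.names = FALSE)
  df <- cbind(feature_id = rownames(table$counts), df)
  rownames(df) <- NULL
  if (!is.null(table$taxonomy)) {
    df$taxonomy <- unname(table$taxonomy[df$feature_id])
  }
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}
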