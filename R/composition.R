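#' Per-sample read depth
#'
#' The read depth of a sample is the sum of its feature counts — the total
#' number of (denoised) reads assigned to it.
#'
#' @param table A [feature_table()].
#' @param sample_id One or more sample ids; defaults to all samples.
#' @return Integer vector of depths, named by sample id.
#' @export
sample_depth <- function(table, sample_id = NULL) {
  stopifnot(inherits(table, "feature_table"))
  ids <- sample_id %||% sample_ids(table)
  unknown <- setdiff(ids, sample_ids(table))
  if (length(unknown)) {
    ks_abort(paste0("Unknown sample id(s): ", paste(head(unknown, 3), collapse = ", ")),
             "unknown_sample")
  }
  d <- colSums(table$counts[, ids, drop = FALSE])
  setNames(as.integer(round(d)), ids)
}

#' Declare an explicit feature-id target
#'
#' Wraps a set of feature ids so that target matching uses them verbatim
#' instead of interpreting a string as a taxonomy substring.
#'
#' @param ids Character vector of feature ids.
#' @return The ids, classed as a `feature_set`.
#' @export
feature_set <- function(ids) {
  structure(as.character(ids), class = "feature_set")
}

#' Features matching a target specification
#'
#' A target specification is either an explicit [feature_set()] (validated
#' and returned verbatim) or a single string matched case-insensitively as a
#' substring of the table's taxonomy lineages — tolerant of Greengenes-style
#' rank prefixes, so `"g__Bacillus"` selects every *Bacillus*-annotated
#' feature.
#'
#' @param table A [feature_table()].
#' @param target_spec A [feature_set()] or a lineage substring.
#' @return Character vector of matching feature ids (possibly empty).
#' @export
match_target_features <- function(table, target_spec) {
  stopifnot(inherits(table, "feature_table"))
  if (inherits(target_spec, "feature_set")) {
    unknown <- setdiff(unclass(target_spec), feature_ids(table))
    if (length(unknown)) {
      ks_abort(paste0("Target feature id(s) not in table: ",
                      paste(head(unknown, 3), collapse = ", ")),
               "unknown_feature")
    }
    return(as.character(target_spec))
  }
  if (!is.character(target_spec) || length(target_spec) != 1L || is.na(target_spec)) {
    ks_abort("`target_spec` must be a feature_set() or a single lineage substring.",
             "invalid_target_spec")
  }
  if (is.null(table$taxonomy)) {
    ks_abort("Substring target spec given but the table has no taxonomy.",
             "no_taxonomy")
  }
  hit <- grepl(target_spec, table$taxonomy, ignore.case = TRUE, fixed = FALSE)
  names(table$taxonomy)[hit]
}

#' Fraction of a sample's reads attributable to the target organism
#'
#' Computed on raw counts as (reads in matched features) / depth, with the
#' division done once on integer sums so that target and non-target fractions
#' add to 1 exactly.
#'
#' @inheritParams sample_depth
#' @inheritParams match_target_features
#' @return Numeric vector in `[0, 1]`, named by sample id.
#' @section Zero-depth samples:
#' Composition is undefined at zero depth; such samples raise an error of
#' class `katharoseq_error_zero_depth` rather than returning 0 or NaN.
#' @export
target_fraction <- function(table, sample_id = NULL, target_spec) {
  stopifnot(inherits(table, "feature_table"))
  ids <- sample_id %||% sample_ids(table)
  depth <- sample_depth(table, ids)
  if (any(depth == 0)) {
    ks_abort(paste0("Composition undefined for zero-depth sample(s): ",
                    paste(head(ids[depth == 0], 3), collapse = ", ")),
             "zero_depth")
  }
  feats <- match_target_features(table, target_spec)
  target_reads <- if (length(feats)) {
    colSums(table$counts[feats, ids, drop = FALSE])
  } else {
    setNames(numeric(length(ids)), ids)
  }
  setNames(as.numeric(target_reads) / as.numeric(depth), ids)
}

#' Assemble composition points for control samples
#'
#' One point per selected sample with positive depth: read depth, target
#' composition, and the known cell input copied from the metadata. Zero-depth
#' samples cannot carry a composition; they are reported in the
#' `zero_depth_samples` attribute (and a message) rather than silently
#' dropped.
#'
#' @param table A [feature_table()].
#' @param design A `katharo_design` (see [study_design()]).
#' @param classes Control classes to include (default: the positive-control
#'   classes).
#' @param target_spec Optional target specification applied to every sample;
#'   when `NULL`, each sample's own `target_spec` from the metadata is used.
#' @return A tibble with columns `sample_id`, `control_class`, `input_cells`,
#'   `depth`, `target_fraction`.
#' @export
composition_points <- function(table, design, classes = POSITIVE_CLASSES,
                               target_spec = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "katharo_design"))
  sel <- design[design$control_class %in% classes &
                  design$sample_id %in% sample_ids(table), , drop = FALSE]
  if (nrow(sel) == 0) {
    out <- tibble(sample_id = character(), control_class = character(),
                  input_cells = numeric(), depth = integer(),
                  target_fraction = numeric())
    attr(out, "zero_depth_samples") <- character()
    return(out)
  }
  depth <- sample_depth(table, sel$sample_id)
  zero <- sel$sample_id[depth == 0]
  if (length(zero)) {
    rlang::inform(paste0(length(zero), " zero-depth sample(s) excluded from composition: ",
                         paste(head(zero, 5), collapse = ", ")))
  }
  keep <- depth > 0
  sel <- sel[keep, , drop = FALSE]
  study_default <- unique(design$target_spec[!is.na(design$target_spec)])
  study_default <- if (length(study_default) == 1) study_default else NULL
  frac <- vapply(seq_len(nrow(sel)), function(i) {
    own <- sel$target_spec[i]
    if (is.na(own)) own <- NULL
    spec <- target_spec %||% own %||% study_default
    if (is.null(spec)) {
      ks_abort(paste0("No target_spec for sample ", sel$sample_id[i]),
               "invalid_target_spec")
    }
    unname(target_fraction(table, sel$sample_id[i], spec))
  }, numeric(1))
  out <- tibble(
    sample_id = sel$sample_id,
    control_class = sel$control_class,
    input_cells = sel$input_cells,
    depth = unname(depth[keep]),
    target_fraction = frac
  )
  attr(out, "zero_depth_samples") <- zero
  out
}
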