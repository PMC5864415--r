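#' Run the full control-based QC pipeline
#'
#' From a feature table and control-annotated metadata: compute control
#' compositions, fit the Hill model against input cells (background load in
#' cell equivalents) and against read depth, determine limits of detection
#' for both the composition and depth metrics, derive a read-count exclusion
#' threshold by the chosen strategy, apply it to every sample, and summarise
#' success rates and contamination. Optionally writes the report to disk:
#' `decisions.tsv` (one row per sample), `summary.json` (the stable machine
#' interface), and `filtered_table.<format>`. Outputs are deterministic:
#' rerunning the same configuration yields byte-identical files.
#'
#' @param table A [feature_table()] or a path to one.
#' @param metadata A `katharo_design` or a path to a TSV sample map.
#' @param target Target specification applied study-wide; defaults to each
#'   positive control's own `target_spec` from the metadata.
#' @param strategy Threshold strategy: `"max_input_median"` (conservative
#'   default — median depth of the top-input positives), `"fit_half_max"`
#'   (permissive — read count at 50% target composition), or `"fixed"`
#'   (caller-supplied `threshold`).
#' @param threshold Read-count threshold, required for `strategy = "fixed"`.
#' @param alpha FDR level for the detection-limit tests.
#' @param ymax_mode Passed to [fit_hill()].
#' @param flag_quantile Passed to [contamination_report()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param format Format of the filtered table (`"tsv"` or `"biom"`).
#' @param quiet Suppress progress messages.
#' @return A `katharo_qc` object (invisibly when writing): fits, LOD
#'   results, threshold, exclusion, success rates, contamination report and
#'   the summary list mirrored into `summary.json`.
#' @section Control design:
#' Threshold strategies need positive extraction controls; detection limits
#' additionally need negatives. A study lacking them fails validation with a
#' reminder of the recommended minimum design: at least 24 positive and 12
#' negative DNA extraction controls per project.
#' @export
run_qc <- function(table, metadata, target = NULL,
                   strategy = c("max_input_median", "fit_half_max", "fixed"),
                   threshold = NULL, alpha = 0.05,
                   ymax_mode = c("free", "fixed_1"), flag_quantile = 0.95,
                   out_dir = NULL, format = c("tsv", "biom"), quiet = FALSE) {
  strategy <- match.arg(strategy)
  ymax_mode <- match.arg(ymax_mode)
  format <- match.arg(format)
  say <- function(...) if (!quiet) rlang::inform(paste0(...))
  if (is.character(table)) table <- read_feature_table(table, format = format)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  stopifnot(inherits(table, "feature_table"), inherits(metadata, "katharo_design"))
  design <- metadata

  pos <- design[design$control_class %in% POSITIVE_CLASSES &
                  design$sample_id %in% sample_ids(table), ]
  if (strategy != "fixed" && nrow(pos) == 0) {
    ks_abort(paste0(
      "Strategy '", strategy, "' needs positive controls with known input ",
      "cells, and none were found. Recommended minimum design: at least 24 ",
      "total positive and 12 negative DNA extraction controls per project."),
      "missing_controls")
  }
  if (strategy == "fixed" && !is_scalar_number(threshold)) {
    ks_abort("Strategy 'fixed' needs a numeric `threshold`.", "invalid_threshold")
  }

  say("Computing control compositions")
  pos_points <- composition_points(table, design, classes = POSITIVE_CLASSES,
                                   target_spec = target)
  # target spec resolved once for fits on negatives/samples too
  spec <- target %||% {
    sp <- unique(design$target_spec[!is.na(design$target_spec)])
    if (length(sp) == 1) sp else NULL
  }
  neg_points <- tryCatch(
    composition_points(table, design, classes = NEGATIVE_CLASSES,
                       target_spec = spec),
    error = function(e) NULL
  )

  ext_points <- pos_points[pos_points$control_class == "extraction_positive", ]
  cells_fit <- NULL
  if (nrow(ext_points) > 0) {
    say("Fitting cells-vs-composition Hill model")
    cells_fit <- tryCatch(
      fit_hill(ext_points, x = "input_cells", y = "target_fraction",
               ymax_mode = ymax_mode, x_variable = "cells"),
      error = function(e) NULL
    )
  }
  reads_fit <- NULL
  if (nrow(pos_points) > 0) {
    say("Fitting reads-vs-composition Hill model")
    reads_fit <- tryCatch(
      fit_hill(pos_points, x = "depth", y = "target_fraction",
               ymax_mode = ymax_mode, x_variable = "reads"),
      error = function(e) NULL
    )
  }

  lod_composition <- lod_depth <- NULL
  if (!is.null(neg_points) && nrow(neg_points) >= 2 && nrow(pos_points) > 0) {
    say("Determining limits of detection")
    lod_composition <- tryCatch(
      limit_of_detection(pos_points, neg_points, metric = "target_fraction",
                         alpha = alpha),
      error = function(e) NULL
    )
    lod_depth <- tryCatch(
      limit_of_detection(pos_points, neg_points, metric = "depth", alpha = alpha),
      error = function(e) NULL
    )
  }

  thr <- switch(strategy,
    fixed = as.integer(ceiling(threshold)),
    max_input_median = threshold_max_input_median(pos_points),
    fit_half_max = {
      if (is.null(reads_fit) || !isTRUE(reads_fit$converged)) {
        ks_abort("Reads-vs-composition fit unavailable; cannot derive half-max threshold.",
                 "unconverged_fit")
      }
      threshold_fit_half_max(reads_fit)
    }
  )
  say("Applying exclusion at ", thr, " reads (", strategy, ")")
  exclusion <- apply_exclusion(table, thr, strategy = strategy)

  rates <- success_rates(exclusion, design)
  contamination <- NULL
  if (!is.null(cells_fit) && isTRUE(cells_fit$converged) && !is.null(spec)) {
    contamination <- contamination_report(table, design, spec, cells_fit,
                                          flag_quantile = flag_quantile)
  }

  summary <- list(
    parameters = list(strategy = strategy, threshold = thr, alpha = alpha,
                      ymax_mode = ymax_mode, target = spec,
                      flag_quantile = flag_quantile),
    n_samples = length(sample_ids(table)),
    n_retained = sum(exclusion$decisions$retained),
    n_excluded = sum(!exclusion$decisions$retained),
    fits = list(
      cells = if (!is.null(cells_fit)) hill_fit_record(cells_fit),
      reads = if (!is.null(reads_fit)) hill_fit_record(reads_fit)
    ),
    limit_of_detection = list(
      target_fraction = if (!is.null(lod_composition))
        as.list(glance(lod_composition)),
      depth = if (!is.null(lod_depth)) as.list(glance(lod_depth))
    ),
    success_rates = rates,
    contamination = if (!is.null(contamination)) list(
      background_cells = contamination$background_cells,
      target_in_negatives = contamination$target_in_negatives,
      target_in_samples = contamination$target_in_samples,
      flagged_samples = contamination$flagged_samples
    )
  )

  res <- structure(
    list(pos_points = pos_points, neg_points = neg_points,
         cells_fit = cells_fit, reads_fit = reads_fit,
         lod_composition = lod_composition, lod_depth = lod_depth,
         threshold = thr, strategy = strategy, exclusion = exclusion,
         success_rates = rates, contamination = contamination,
         summary = summary),
    class = "katharo_qc"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(exclusion$decisions, file.path(out_dir, "decisions.tsv"),
                     progress = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", dataframe = "rows")
    write_feature_table(exclusion$table,
                        file.path(out_dir, paste0("filtered_table.", format)),
                        format = format)
    say("Report written to ", out_dir)
    return(invisible(res))
  }
  res
}

#' @export
print.katharo_qc <- function(x, ...) {
  cat("<katharo_qc>\n")
  if (!is.null(x$cells_fit) && isTRUE(x$cells_fit$converged)) {
    cat(sprintf("  background load: %.4g cell equivalents (R^2 = %.3f)\n",
                x$cells_fit$k_half, x$cells_fit$r_squared))
  }
  if (!is.null(x$lod_composition)) {
    cat(sprintf("  LOD (composition): %s cells\n",
                format(x$lod_composition$lod_cells)))
  }
  if (!is.null(x$lod_depth)) {
    cat(sprintf("  LOD (depth): %s cells\n", format(x$lod_depth$lod_cells)))
  }
  cat(sprintf("  exclusion: threshold %d reads (%s), %d/%d samples retained\n",
              x$threshold, x$strategy, sum(x$exclusion$decisions$retained),
              nrow(x$exclusion$decisions)))
  invisible(x)
}

#' Simulate a study and write it to disk
#'
#' Thin wrapper over [generate_study()] + [write_simulated_study()]; the
#' written files are directly consumable by [run_qc()].
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed (overrides `params$seed`; the seed actually used
#'   is recorded in the manifest).
#' @param out_dir Output directory.
#' @param format Feature-table format.
#' @return The `katharo_simulation`, invisibly.
#' @export
simulate_study <- function(params = simulation_params(), seed = NULL,
                           out_dir, format = c("tsv", "biom")) {
  format <- match.arg(format)
  sim <- generate_study(params, seed = seed)
  write_simulated_study(sim, out_dir, format = format)
  invisible(sim)
}
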