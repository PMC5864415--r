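#' Read-count threshold from the half-maximum of a reads-vs-composition fit
#'
#' Inverts the fitted curve at a target composition of 0.5: the read count at
#' which half of a positive control's reads map to the expected organism.
#' When `ymax = 1` this is exactly `k_half`. The value is rounded up to an
#' integer so the threshold is a realizable read count.
#'
#' @param reads_fit A converged `hill_fit` with `x_variable = "reads"`.
#' @return Integer read-count threshold.
#' @section When the curve never reaches 50%:
#' If `ymax <= 0.5` the half-maximum composition is unattainable and an
#' error of class `katharoseq_error_unreachable_half` is raised, pointing at
#' [threshold_max_input_median()] as the fallback.
#' @export
threshold_fit_half_max <- function(reads_fit) {
  stopifnot(inherits(reads_fit, "hill_fit"))
  if (!isTRUE(reads_fit$converged)) {
    ks_abort("Fit did not converge; no threshold derived.", "unconverged_fit")
  }
  if (reads_fit$x_variable != "reads") {
    ks_abort("Half-max threshold needs a reads-vs-composition fit.",
             "wrong_x_variable")
  }
  if (reads_fit$ymax <= 0.5) {
    ks_abort(paste0("Fitted ymax = ", signif(reads_fit$ymax, 3),
                    " never reaches a 50% target composition; use ",
                    "threshold_max_input_median() instead."),
             "unreachable_half")
  }
  # guard against float noise so an integer k_half maps to itself
  as.integer(ceiling(invert_hill(reads_fit, 0.5) - 1e-8))
}

#' Read-count threshold from the maximum-input controls
#'
#' The conservative strategy: the median read depth of positive controls at
#' the largest titration level. With an even number of controls the lower of
#' the two central depths is taken, keeping the threshold an observed
#' (integer) depth and erring on the permissive side of the median pair.
#'
#' @param points Composition points of positive controls (columns
#'   `input_cells`, `depth`).
#' @return Integer read-count threshold.
#' @export
threshold_max_input_median <- function(points) {
  points <- as_tibble(points)
  pts <- points[!is.na(points$input_cells), , drop = FALSE]
  if (nrow(pts) == 0) {
    ks_abort("No positive controls with known input_cells.", "missing_controls")
  }
  top <- pts$depth[pts$input_cells == max(pts$input_cells)]
  as.integer(median_lower(top))
}

#' Apply a read-count exclusion threshold
#'
#' Every sample in the table receives exactly one decision; a sample is
#' retained when its depth is at least the threshold (boundary inclusive).
#' Counts of retained samples are untouched — the method excludes samples,
#' never renormalizes or removes features.
#'
#' @param table A [feature_table()].
#' @param threshold Positive read-count threshold.
#' @param strategy Label recording how the threshold was derived
#'   (`"max_input_median"`, `"fit_half_max"` or `"fixed"`).
#' @return A `katharo_exclusion`: `$decisions` (tibble: `sample_id`, `depth`,
#'   `threshold`, `retained`, `strategy`) and `$table` (the filtered
#'   [feature_table()] holding exactly the retained samples).
#' @export
apply_exclusion <- function(table, threshold,
                            strategy = c("max_input_median", "fit_half_max", "fixed")) {
  stopifnot(inherits(table, "feature_table"))
  strategy <- match.arg(strategy)
  if (!is_scalar_number(threshold) || threshold <= 0) {
    ks_abort("`threshold` must be a positive number.", "invalid_threshold")
  }
  depth <- sample_depth(table)
  decisions <- tibble(
    sample_id = names(depth),
    depth = unname(depth),
    threshold = threshold,
    retained = unname(depth) >= threshold,
    strategy = strategy
  )
  kept <- decisions$sample_id[decisions$retained]
  filtered <- feature_table(table$counts[, kept, drop = FALSE],
                            taxonomy = table$taxonomy)
  structure(list(decisions = decisions, table = filtered,
                 threshold = threshold, strategy = strategy),
            class = "katharo_exclusion")
}

#' @export
print.katharo_exclusion <- function(x, ...) {
  n <- nrow(x$decisions)
  k <- sum(x$decisions$retained)
  cat(sprintf("<katharo_exclusion> threshold %g reads (%s): %d of %d samples retained\n",
              x$threshold, x$strategy, k, n))
  invisible(x)
}

#' Per-sample decisions of an exclusion
#' @param x A `katharo_exclusion`.
#' @param ... Unused.
#' @export
tidy.katharo_exclusion <- function(x, ...) x$decisions

#' One-row summary of an exclusion
#' @param x A `katharo_exclusion`.
#' @param ... Unused.
#' @export
glance.katharo_exclusion <- function(x, ...) {
  tibble(threshold = x$threshold, strategy = x$strategy,
         n_samples = nrow(x$decisions), n_retained = sum(x$decisions$retained),
         n_excluded = sum(!x$decisions$retained))
}

#' Plot sample depths against the exclusion threshold
#' @param object A `katharo_exclusion`.
#' @param ... Unused.
#' @export
autoplot.katharo_exclusion <- function(object, ...) {
  d <- object$decisions
  d <- d[order(d$depth), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$depth + 1,
                                  colour = .data$retained)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "samples (by depth)", y = "read depth + 1",
                  subtitle = sprintf("threshold %g reads (%s)",
                                     object$threshold, object$strategy)) +
    ggplot2::theme_minimal()
}

#' Proportion of retained samples in a subset
#'
#' @param decisions Decision tibble (or a `katharo_exclusion`).
#' @param sample_ids Ids defining the subset; must be nonempty and covered by
#'   the decisions.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(decisions, sample_ids) {
  if (inherits(decisions, "katharo_exclusion")) decisions <- decisions$decisions
  if (length(sample_ids) == 0) {
    ks_abort("Empty subset.", "empty_subset")
  }
  missing <- setdiff(sample_ids, decisions$sample_id)
  if (length(missing)) {
    ks_abort(paste0("No decision for sample(s): ",
                    paste(head(missing, 3), collapse = ", ")), "unknown_sample")
  }
  sub <- decisions[decisions$sample_id %in% sample_ids, , drop = FALSE]
  mean(sub$retained)
}

#' Success rates per control class
#'
#' @param decisions Decision tibble (or a `katharo_exclusion`).
#' @param design A `katharo_design`.
#' @return Tibble with `control_class`, `n`, `n_retained`, `success_rate`.
#' @export
success_rates <- function(decisions, design) {
  if (inherits(decisions, "katharo_exclusion")) decisions <- decisions$decisions
  stopifnot(inherits(design, "katharo_design"))
  dplyr::inner_join(decisions, as_tibble(design)[, c("sample_id", "control_class")],
                    by = "sample_id") |>
    dplyr::group_by(.data$control_class) |>
    dplyr::summarise(n = dplyr::n(), n_retained = sum(.data$retained),
                     success_rate = mean(.data$retained), .groups = "drop")
}

#' False-negativity of gel-based library QC
#'
#' Compares gel-band visibility against read-count retention: the
#' false-negativity rate is the share of read-retained libraries that showed
#' no visible band — libraries a gel-based QC would wrongly have discarded.
#'
#' @param decisions Decision tibble (or a `katharo_exclusion`).
#' @param band_flags Named logical vector (visible band yes/no) covering
#'   every library in the decisions.
#' @return One-row tibble: `n_retained`, `n_retained_banded`,
#'   `n_retained_no_band`, `n_banded_excluded`, `false_negativity`.
#'   Banded-but-excluded libraries are counted and reported (with a message)
#'   rather than hidden.
#' @export
gel_comparison <- function(decisions, band_flags) {
  if (inherits(decisions, "katharo_exclusion")) decisions <- decisions$decisions
  missing <- setdiff(decisions$sample_id, names(band_flags))
  if (length(missing)) {
    ks_abort(paste0("No band flag for library(ies): ",
                    paste(head(missing, 3), collapse = ", ")), "incomplete_bands")
  }
  bands <- band_flags[decisions$sample_id]
  retained <- decisions$retained
  if (!any(retained)) {
    ks_abort("No read-retained libraries; false-negativity undefined.",
             "empty_subset")
  }
  n_ret <- sum(retained)
  n_ret_band <- sum(retained & bands)
  n_band_excl <- sum(!retained & bands)
  if (n_band_excl > 0) {
    rlang::inform(paste0(n_band_excl,
                         " banded library(ies) fell below the read threshold."))
  }
  tibble(
    n_retained = n_ret,
    n_retained_banded = n_ret_band,
    n_retained_no_band = n_ret - n_ret_band,
    n_banded_excluded = n_band_excl,
    false_negativity = (n_ret - n_ret_band) / n_ret
  )
}

#' Contamination summary for a study
#'
#' Reports the background contamination load in cell equivalents (the
#' half-saturation constant of the cells-vs-composition fit) together with
#' how much of the control organism shows up where it should not: target
#' composition summaries in negative controls and in true samples, and the
#' samples whose target fraction exceeds a quantile of the negatives'
#' distribution (candidate well-to-well contamination).
#'
#' @param table A [feature_table()].
#' @param design A `katharo_design`.
#' @param target_spec Target specification (see [match_target_features()]).
#' @param cells_fit A converged `hill_fit` with `x_variable = "cells"`.
#' @param flag_quantile Quantile of the negatives' target fraction above
#'   which a true sample is flagged (default 0.95).
#' @return A `contamination_report` list: `background_cells`,
#'   `target_in_negatives`, `target_in_samples` (summary tibbles, `NULL`
#'   when the class is absent), `flagged_samples`, `flag_quantile`.
#' @export
contamination_report <- function(table, design, target_spec, cells_fit,
                                 flag_quantile = 0.95) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "katharo_design"),
            inherits(cells_fit, "hill_fit"))
  if (cells_fit$x_variable != "cells") {
    ks_abort("`cells_fit` must be a cells-vs-composition fit.", "wrong_x_variable")
  }
  frac_for <- function(classes) {
    ids <- design$sample_id[design$control_class %in% classes]
    ids <- intersect(ids, sample_ids(table))
    ids <- ids[sample_depth(table, ids) > 0]
    if (length(ids) == 0) return(NULL)
    target_fraction(table, ids, target_spec)
  }
  summarise_frac <- function(fr) {
    if (is.null(fr)) return(NULL)
    tibble(n = length(fr), median = median(fr), mean = mean(fr),
           q95 = unname(quantile(fr, 0.95)), max = max(fr))
  }
  neg <- frac_for(NEGATIVE_CLASSES)
  smp <- frac_for("sample")
  flagged <- character()
  if (!is.null(neg) && !is.null(smp)) {
    cut <- unname(quantile(neg, flag_quantile))
    flagged <- names(smp)[smp > cut]
  }
  structure(
    list(background_cells = cells_fit$k_half,
         target_in_negatives = summarise_frac(neg),
         target_in_samples = summarise_frac(smp),
         flagged_samples = flagged,
         flag_quantile = flag_quantile),
    class = "contamination_report"
  )
}

#' @export
print.contamination_report <- function(x, ...) {
  cat(sprintf("<contamination_report> background load: %.4g cell equivalents\n",
              x$background_cells))
  if (!is.null(x$target_in_negatives)) {
    cat(sprintf("  target in negatives: median %.4g (n = %d)\n",
                x$target_in_negatives$median, x$target_in_negatives$n))
  }
  if (!is.null(x$target_in_samples)) {
    cat(sprintf("  target in samples:   median %.4g (n = %d)\n",
                x$target_in_samples$median, x$target_in_samples$n))
  }
  if (length(x$flagged_samples)) {
    cat("  flagged:", paste(head(x$flagged_samples, 5), collapse = ", "),
        if (length(x$flagged_samples) > 5) "..." else "", "\n")
  }
  invisible(x)
}
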