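#' Kruskal-Wallis rank test
#'
#' Nonparametric comparison of two or more groups by ranks, with midrank tie
#' handling and the tie-corrected statistic. The default p-value comes from
#' the chi-square approximation (df = groups - 1) via [stats::kruskal.test()];
#' for two small groups an exact permutation p-value is available (and is
#' used automatically when the total n is below 8, where the chi-square
#' approximation is unreliable).
#'
#' @param values Either a list of numeric vectors (one per group) or a
#'   numeric vector accompanied by `groups`.
#' @param groups Group labels, when `values` is a single vector.
#' @param exact `NULL` (auto: exact for 2 groups with total n < 8), `TRUE`
#'   (force exact; 2 groups only), or `FALSE`.
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(values, groups = NULL, exact = NULL) {
  if (is.list(values) && is.null(groups)) {
    g <- rep(seq_along(values), lengths(values))
    v <- unlist(values, use.names = FALSE)
  } else {
    v <- values
    g <- groups
  }
  if (is.null(g) || length(v) != length(g)) {
    ks_abort("Provide a list of groups, or values plus matching group labels.",
             "malformed_groups")
  }
  g <- factor(g)
  if (nlevels(g) < 2 || any(tabulate(g) == 0) || length(v) < 3) {
    ks_abort("Need >= 2 nonempty groups and total n >= 3.", "malformed_groups")
  }
  if (length(unique(v)) == 1) {
    return(tibble(statistic = 0, p_value = 1, df = nlevels(g) - 1L,
                  method = "degenerate"))
  }
  use_exact <- if (is.null(exact)) nlevels(g) == 2 && length(v) < 8 else isTRUE(exact)
  if (use_exact && nlevels(g) != 2) {
    ks_abort("Exact permutation p-values are implemented for 2 groups only.",
             "unsupported_exact")
  }
  if (use_exact) {
    res <- kw_exact_two_group(v, g)
    return(tibble(statistic = res$statistic, p_value = res$p_value,
                  df = 1L, method = "exact permutation"))
  }
  kt <- kruskal.test(v, g)
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
         df = unname(kt$parameter), method = "chi-square approximation")
}

# Tie-corrected KW statistic for every split of the pooled ranks into groups
# of the observed sizes; p = share of splits with a statistic at least as
# large as observed. Enumerates all choose(n, n1) assignments.
kw_exact_two_group <- function(v, g) {
  n <- length(v)
  r <- rank(v)
  n1 <- sum(g == levels(g)[1])
  ties <- table(v)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(R1) {
    R2 <- sum(r) - R1
    h <- 12 / (n * (n + 1)) * (R1^2 / n1 + R2^2 / (n - n1)) - 3 * (n + 1)
    h / cf
  }
  h_obs <- h_of(sum(r[g == levels(g)[1]]))
  combos <- utils::combn(n, n1)
  r1 <- matrix(r[combos], nrow = n1)
  h_all <- h_of(colSums(r1))
  list(statistic = h_obs, p_value = mean(h_all >= h_obs - 1e-10))
}

#' Benjamini-Hochberg step-up decisions
#'
#' Adjusts p-values by the BH step-up procedure and reports which are
#' rejected at FDR level `alpha`: reject hypotheses `1..i*` (in order of
#' increasing p) where `i*` is the largest `i` with `p(i) <= i * alpha / m`.
#' The boundary is inclusive: an adjusted value exactly equal to `alpha` is
#' rejected.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A tibble in input order: `p_value`, `q_value` (BH-adjusted),
#'   `reject`. Empty input gives an empty tibble.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(tibble(p_value = numeric(), q_value = numeric(), reject = logical()))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, q_value = q, reject = !is.na(q) & q <= alpha)
}

#' Limit of detection from titrated controls
#'
#' Tests each titration level against the pooled negative controls with a
#' two-group Kruskal-Wallis test on the chosen metric, controls the FDR
#' across levels with Benjamini-Hochberg, and reports the limit of detection
#' as the smallest level from which every larger (testable) level is also
#' significant — so a spuriously significant isolated low level cannot drive
#' the LOD down.
#'
#' @param points Composition points of the positive controls (from
#'   [composition_points()]); must carry `input_cells` and the metric column.
#' @param negatives Composition points of the negative controls.
#' @param metric `"target_fraction"` (default) or `"depth"`.
#' @param alpha FDR level (default 0.05).
#' @return A `lod_result`: per-level tests and `lod_cells` (`NA` when no
#'   level qualifies). Levels with fewer than 2 usable points are marked
#'   untestable and excluded from the BH family (with a message).
#' @export
limit_of_detection <- function(points, negatives,
                               metric = c("target_fraction", "depth"),
                               alpha = 0.05) {
  metric <- match.arg(metric)
  points <- as_tibble(points)
  negatives <- as_tibble(negatives)
  levels_ <- sort(unique(points$input_cells[!is.na(points$input_cells)]))
  if (length(levels_) < 2) {
    ks_abort("Need at least 2 titration levels.", "insufficient_levels")
  }
  neg_vals <- negatives[[metric]]
  neg_vals <- neg_vals[is.finite(neg_vals)]
  if (length(neg_vals) < 2) {
    ks_abort("Need at least 2 negative controls.", "insufficient_negatives")
  }
  per <- purrr::map_dfr(levels_, function(lv) {
    vals <- points[[metric]][!is.na(points$input_cells) & points$input_cells == lv]
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2) {
      return(tibble(input_cells = lv, n = length(vals),
                    kw_statistic = NA_real_, p_value = NA_real_,
                    testable = FALSE))
    }
    kt <- kruskal_wallis(list(vals, neg_vals))
    tibble(input_cells = lv, n = length(vals),
           kw_statistic = kt$statistic, p_value = kt$p_value, testable = TRUE)
  })
  if (any(!per$testable)) {
    rlang::inform(paste0("Untestable level(s) (fewer than 2 points), excluded from FDR family: ",
                         paste(per$input_cells[!per$testable], collapse = ", ")))
  }
  adj <- bh_adjust(per$p_value[per$testable], alpha = alpha)
  per$q_value <- NA_real_
  per$reject <- NA
  per$q_value[per$testable] <- adj$q_value
  per$reject[per$testable] <- adj$reject
  # smallest level with itself and every larger testable level rejected
  test_lv <- per[per$testable, ]
  lod <- NA_real_
  if (nrow(test_lv)) {
    ok <- rev(cumprod(rev(test_lv$reject))) == 1
    if (any(ok)) lod <- min(test_lv$input_cells[ok])
  }
  values <- dplyr::bind_rows(
    tibble(input_cells = points$input_cells, value = points[[metric]],
           group = "positive"),
    tibble(input_cells = NA_real_, value = neg_vals, group = "negative")
  )
  structure(
    list(metric = metric, alpha = alpha, per_level = per, lod_cells = lod,
         n_negatives = length(neg_vals), data = values),
    class = "lod_result"
  )
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> metric: %s, FDR alpha = %g, %d negatives\n",
              x$metric, x$alpha, x$n_negatives))
  print(x$per_level)
  cat(if (is.na(x$lod_cells)) "  no level distinguishable from negatives\n"
      else sprintf("  limit of detection: %g cells\n", x$lod_cells))
  invisible(x)
}

#' Per-level test table of an LOD analysis
#' @param x A `lod_result`.
#' @param ... Unused.
#' @export
tidy.lod_result <- function(x, ...) x$per_level

#' One-row summary of an LOD analysis
#' @param x A `lod_result`.
#' @param ... Unused.
#' @export
glance.lod_result <- function(x, ...) {
  tibble(metric = x$metric, alpha = x$alpha,
         n_levels = nrow(x$per_level), n_negatives = x$n_negatives,
         lod_cells = x$lod_cells)
}

#' Plot titration levels against negatives
#' @param object A `lod_result`.
#' @param ... Unused.
#' @export
autoplot.lod_result <- function(object, ...) {
  d <- object$data
  d$level <- ifelse(d$group == "negative", "neg",
                    format(d$input_cells, trim = TRUE, scientific = FALSE))
  d$level <- factor(d$level, levels = c("neg", format(sort(unique(
    d$input_cells[!is.na(d$input_cells)])), trim = TRUE, scientific = FALSE)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "input cells", y = object$metric,
                  subtitle = if (is.na(object$lod_cells)) "no detectable level"
                  else sprintf("limit of detection: %g cells", object$lod_cells)) +
    ggplot2::theme_minimal()
}
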