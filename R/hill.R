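#' The allosteric sigmoidal (Hill) curve
#'
#' `y = ymax * x^h / (k_half^h + x^h)`: a saturating dose-response curve used
#' here to describe how the target organism's share of reads grows with input
#' biomass. `k_half` is the half-saturation constant — the input (cells, or
#' reads) at which the curve reaches `ymax / 2`. In a cells-vs-composition
#' fit it is interpreted as the background contamination load in cell
#' equivalents; in a reads-vs-composition fit, as a read-count exclusion
#' threshold.
#'
#' @param x Non-negative input(s): cells or reads.
#' @param ymax Curve maximum, in `(0, 1]`.
#' @param k_half Half-saturation constant, positive.
#' @param h Hill coefficient (steepness), positive.
#' @return `y` values in `[0, ymax)`; `y(0) = 0`.
#' @examples
#' hill_curve(96.88, ymax = 1, k_half = 96.88, h = 1.37)  # = 0.5
#' @export
hill_curve <- function(x, ymax, k_half, h) {
  if (any(x < 0, na.rm = TRUE)) {
    ks_abort("`x` must be non-negative.", "negative_x")
  }
  stopifnot(ymax > 0, ymax <= 1, k_half > 0, h > 0)
  t <- (x / k_half)^h
  ifelse(is.infinite(t), ymax, ymax * t / (1 + t))
}

#' Closed-form Hill parameters through two points
#'
#' Solves for `(k_half, h)` so that the Hill curve with the given `ymax`
#' passes exactly through `(x1, y1)` and `(x2, y2)`. Writing
#' `r(y) = y / (ymax - y)`, the solution is
#' `h = log(r(y2)/r(y1)) / log(x2/x1)` and `k_half = x1 * r(y1)^(-1/h)`.
#'
#' @param x1,x2 Inputs with `0 < x1 < x2`.
#' @param y1,y2 Responses with `0 < y1 < y2 < ymax`.
#' @param ymax Curve maximum (default 1).
#' @return A list with components `k_half` and `h`.
#' @examples
#' # mean target compositions at 50 and 500 cells
#' solve_two_point(50, 0.288, 500, 0.906)
#' @export
solve_two_point <- function(x1, y1, x2, y2, ymax = 1) {
  ok <- is_scalar_number(x1) && is_scalar_number(x2) &&
    is_scalar_number(y1) && is_scalar_number(y2) && is_scalar_number(ymax)
  if (!ok || !(0 < x1 && x1 < x2) || !(0 < y1 && y1 < y2 && y2 < ymax)) {
    ks_abort("Need 0 < x1 < x2 and 0 < y1 < y2 < ymax.", "degenerate_points")
  }
  r1 <- y1 / (ymax - y1)
  r2 <- y2 / (ymax - y2)
  h <- log(r2 / r1) / log(x2 / x1)
  k_half <- x1 * r1^(-1 / h)
  list(k_half = k_half, h = h)
}

new_hill_fit <- function(ymax, k_half, h, r_squared, n_points, x_variable,
                         converged, ymax_mode, data) {
  structure(
    list(ymax = ymax, k_half = k_half, h = h, r_squared = r_squared,
         n_points = n_points, x_variable = x_variable, converged = converged,
         ymax_mode = ymax_mode, data = data),
    class = "hill_fit"
  )
}

#' Fit the Hill model to composition points
#'
#' Least-squares fit of `y = ymax * x^h / (k_half^h + x^h)` on linear `x`,
#' using bounded Levenberg-Marquardt (via minpack.lm). Initial values come
#' from the closed-form two-point solution through the mean responses at the
#' smallest and largest `x` levels, so the fit is deterministic. Bounds:
#' `k_half > 0`, `h` in `(0.1, 10]`, `ymax` in `(0, 1]`.
#'
#' @param data A data frame of points.
#' @param x,y Names of the input and response columns (defaults `"x"`,
#'   `"y"`); responses must lie in `[0, 1]`.
#' @param ymax_mode `"free"` (default; `ymax` estimated, bounded above by 1)
#'   or `"fixed_1"` (`ymax` pinned to 1, as in the two-point reconstruction).
#' @param weights Optional: a numeric vector of per-point weights, the name
#'   of a weight column, or `"binomial"` to weight by `depth / (y(1-y))`
#'   (requires a `depth` column) — the inverse binomial variance of a
#'   proportion.
#' @param x_variable What `x` measures: `"cells"` or `"reads"`. Purely a
#'   label, carried into downstream interpretation of `k_half`.
#' @return A `hill_fit` object: parameters, `r_squared`
#'   (`1 - SSres/SStot`, unweighted), `n_points`, `converged`, and the data.
#'   Degenerate input (no variance in `y`) returns an unconverged fit with
#'   `NA` parameters rather than a spurious curve.
#' @seealso [solve_two_point()], [invert_hill()], [tidy()], [glance()],
#'   [autoplot()]
#' @export
fit_hill <- function(data, x = "x", y = "y", ymax_mode = c("free", "fixed_1"),
                     weights = NULL, x_variable = c("cells", "reads")) {
  ymax_mode <- match.arg(ymax_mode)
  x_variable <- match.arg(x_variable)
  data <- as.data.frame(data)
  xs <- data[[x]]
  ys <- data[[y]]
  if (is.null(xs) || is.null(ys)) {
    ks_abort("Columns for `x` and `y` not found in `data`.", "malformed_header")
  }
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (any(ys < 0 | ys > 1)) {
    ks_abort("Responses must lie in [0, 1].", "out_of_range")
  }
  pts <- tibble(x = xs, y = ys)
  need <- if (ymax_mode == "free") 3L else 2L
  if (length(unique(xs)) < need) {
    ks_abort(paste0("Need at least ", need, " distinct x levels for ymax_mode = '",
                    ymax_mode, "'."), "insufficient_points")
  }
  if (stats::var(ys) == 0) {
    return(new_hill_fit(NA_real_, NA_real_, NA_real_, NA_real_, length(ys),
                        x_variable, converged = FALSE, ymax_mode, pts))
  }
  w <- resolve_weights(weights, data[keep, , drop = FALSE], ys)

  start <- hill_start(xs, ys, ymax_mode)
  lower <- c(k_half = 1e-9, h = 0.1)
  upper <- c(k_half = Inf, h = 10)
  if (ymax_mode == "free") {
    lower <- c(ymax = 1e-6, lower)
    upper <- c(ymax = 1, upper)
  }
  fml <- if (ymax_mode == "free") {
    y ~ ymax * (x / k_half)^h / (1 + (x / k_half)^h)
  } else {
    y ~ (x / k_half)^h / (1 + (x / k_half)^h)
  }
  # a short fixed ladder of starts keeps the fit deterministic while avoiding
  # the ymax upper bound trapping the free fit at initialization
  starts <- list(start)
  if (ymax_mode == "free") {
    starts <- c(starts, list(
      modifyList(start, list(ymax = max(0.5, 0.9 * start$ymax))),
      modifyList(start, list(ymax = max(0.5, 0.9 * start$ymax), h = 1))
    ))
  }
  fit <- NULL
  best_ss <- Inf
  for (st in starts) {
    st$ymax <- if (!is.null(st$ymax)) min(st$ymax, 1 - 1e-9)
    nls_args <- list(
      fml, data = pts, start = st,
      lower = lower[names(st)], upper = upper[names(st)],
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-10,
                                           maxiter = 500)
    )
    if (!is.null(w)) nls_args$weights <- w
    cand <- tryCatch(do.call(minpack.lm::nlsLM, nls_args),
                     error = function(e) NULL)
    if (!is.null(cand)) {
      ss <- sum(stats::resid(cand)^2)
      if (ss < best_ss) {
        best_ss <- ss
        fit <- cand
      }
    }
  }
  if (is.null(fit)) {
    return(new_hill_fit(NA_real_, NA_real_, NA_real_, NA_real_, length(ys),
                        x_variable, converged = FALSE, ymax_mode, pts))
  }
  est <- coef(fit)
  ymax_hat <- if (ymax_mode == "free") unname(est["ymax"]) else 1
  k_hat <- unname(est["k_half"])
  h_hat <- unname(est["h"])
  r2 <- r_squared_values(ys, hill_curve(xs, ymax_hat, k_hat, h_hat))
  new_hill_fit(ymax_hat, k_hat, h_hat, r2, length(ys), x_variable,
               converged = fit$convInfo$isConv, ymax_mode, pts)
}

resolve_weights <- function(weights, data, ys) {
  if (is.null(weights)) return(NULL)
  if (is.numeric(weights)) {
    stopifnot(length(weights) == length(ys))
    return(weights)
  }
  if (identical(weights, "binomial")) {
    if (is.null(data$depth)) {
      ks_abort("Binomial weights need a `depth` column.", "malformed_header")
    }
    p <- pmin(pmax(ys, 1e-6), 1 - 1e-6)
    return(data$depth / (p * (1 - p)))
  }
  if (is.character(weights) && weights %in% names(data)) {
    return(data[[weights]])
  }
  ks_abort("Unusable `weights` argument.", "invalid_weights")
}

# Deterministic initialization: two-point closed form through the mean
# responses at the extreme x levels, falling back to midrange guesses when
# those means are not strictly increasing.
hill_start <- function(xs, ys, ymax_mode) {
  ymax0 <- if (ymax_mode == "free") min(1, max(ys) * 1.02 + 1e-6) else 1
  lv <- sort(unique(xs))
  x1 <- lv[1]; x2 <- lv[length(lv)]
  y1 <- mean(ys[xs == x1]); y2 <- mean(ys[xs == x2])
  ok <- x1 > 0 && y1 > 0 && y2 > y1 && y2 < ymax0
  init <- if (ok) {
    tryCatch(solve_two_point(x1, y1, x2, y2, ymax = ymax0),
             error = function(e) NULL)
  } else {
    NULL
  }
  if (is.null(init)) init <- list(k_half = median(xs[xs > 0]), h = 1)
  init$h <- min(max(init$h, 0.11), 10)
  init$k_half <- max(init$k_half, 1e-6)
  if (ymax_mode == "free") {
    c(list(ymax = ymax0), init)
  } else {
    init
  }
}

r_squared_values <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    ks_abort("R-squared undefined: responses have zero variance.", "zero_variance")
  }
  1 - sum((obs - pred)^2) / ss_tot
}

#' Coefficient of determination of a Hill fit
#'
#' `1 - SSres/SStot`, with `SStot` about the mean response. Can be negative
#' when the curve fits worse than the constant mean.
#'
#' @param data Data frame of points.
#' @param fit A `hill_fit`.
#' @param x,y Column names (defaults `"x"`, `"y"`).
#' @return A number `<= 1`.
#' @export
hill_r_squared <- function(data, fit, x = "x", y = "y") {
  stopifnot(inherits(fit, "hill_fit"))
  data <- as.data.frame(data)
  r_squared_values(data[[y]], hill_curve(data[[x]], fit$ymax, fit$k_half, fit$h))
}

#' Invert a fitted Hill curve
#'
#' Returns the `x` at which the fitted curve attains a response `y`:
#' `x = k_half * (y / (ymax - y))^(1/h)`. Inverting a reads-vs-composition
#' fit at `y = 0.5` gives the read count at which half the reads come from
#' the true signal — the basis of the half-maximum exclusion threshold.
#'
#' @param fit A converged `hill_fit`.
#' @param y Response value(s) strictly between 0 and `ymax`.
#' @return `x` value(s) on the fit's input scale.
#' @export
invert_hill <- function(fit, y) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) {
    ks_abort("Cannot invert an unconverged fit.", "unconverged_fit")
  }
  if (any(y <= 0 | y >= fit$ymax)) {
    ks_abort("`y` must lie strictly between 0 and ymax.", "out_of_range")
  }
  fit$k_half * (y / (fit$ymax - y))^(1 / fit$h)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> y = ymax * x^h / (k_half^h + x^h)   [x: %s]\n",
              x$x_variable))
  if (isTRUE(x$converged)) {
    cat(sprintf("  ymax = %.4f  k_half = %.4g  h = %.4f  (ymax %s)\n",
                x$ymax, x$k_half, x$h,
                if (x$ymax_mode == "free") "free" else "fixed at 1"))
    cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, x$n_points))
  } else {
    cat("  fit refused or not converged\n")
  }
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$data$x else {
    if (is.data.frame(newdata)) newdata$x else newdata
  }
  hill_curve(xs, object$ymax, object$k_half, object$h)
}

#' Tidy a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ymax", "k_half", "h"),
         estimate = c(x$ymax, x$k_half, x$h))
}

#' One-row summary of a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n_points = x$n_points,
         x_variable = x$x_variable, ymax_mode = x$ymax_mode,
         converged = x$converged)
}

#' Flat record of a Hill fit for serialization
#' @param fit A `hill_fit`.
#' @return A named list of scalars suitable for JSON output.
#' @export
hill_fit_record <- function(fit) {
  stopifnot(inherits(fit, "hill_fit"))
  list(ymax = fit$ymax, k_half = fit$k_half, h = fit$h,
       r_squared = fit$r_squared, n_points = fit$n_points,
       x_variable = fit$x_variable, ymax_mode = fit$ymax_mode,
       converged = fit$converged)
}

#' Plot a Hill fit
#'
#' Control points and the fitted curve on a log10 input axis.
#'
#' @param object A converged `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  stopifnot(inherits(object, "hill_fit"))
  pts <- object$data[object$data$x > 0, , drop = FALSE]
  grid <- tibble(x = exp(seq(log(min(pts$x)), log(max(pts$x)), length.out = 200)))
  grid$y <- predict(object, grid)
  xlab <- if (object$x_variable == "cells") "input cells" else "read depth"
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$ymax / 2, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$k_half, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = "target composition",
                  subtitle = sprintf("k_half = %.4g %s, h = %.2f, R² = %.3f",
                                     object$k_half, object$x_variable,
                                     object$h, object$r_squared)) +
    ggplot2::theme_minimal()
}
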