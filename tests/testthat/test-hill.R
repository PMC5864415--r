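test_that("hill_curve obeys the half-saturation identity and limits", {
  expect_equal(hill_curve(96.88, 1, 96.88, 1.37), 0.5)
  expect_equal(hill_curve(0, 0.8, 10, 2), 0)
  # direct arithmetic at the 500-cell input of the reconstructed curve
  expect_equal(hill_curve(500, 1, 96.88, 1.3685), 0.904, tolerance = 1e-3)
  expect_error(hill_curve(-1, 1, 10, 1), class = "katharoseq_error_negative_x")
})

test_that("hill_curve is strictly increasing on positive x", {
  set.seed(3)
  for (i in 1:20) {
    k <- runif(1, 0.5, 2000)
    h <- runif(1, 0.15, 8)
    ymax <- runif(1, 0.2, 1)
    x <- sort(runif(50, 0.01, 10000))
    y <- hill_curve(x, ymax, k, h)
    expect_true(all(diff(y) >= 0))       # numerically saturates at ymax
    expect_true(all(y >= 0 & y < ymax))
    xm <- sort(runif(20, k / 4, 4 * k))  # strictly increasing off saturation
    expect_true(all(diff(hill_curve(xm, ymax, k, h)) > 0))
  }
})

test_that("two-point solver passes exactly through its inputs and recovers known curves", {
  sol <- solve_two_point(50, 0.288, 500, 0.906)
  expect_equal(hill_curve(50, 1, sol$k_half, sol$h), 0.288, tolerance = 1e-12)
  expect_equal(hill_curve(500, 1, sol$k_half, sol$h), 0.906, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    k <- runif(1, 1, 1000); h <- runif(1, 0.3, 5); ymax <- runif(1, 0.5, 1)
    x <- sort(runif(2, 1, 5000))
    if (diff(x) < 1) next
    y <- hill_curve(x, ymax, k, h)
    sol <- solve_two_point(x[1], y[1], x[2], y[2], ymax = ymax)
    expect_equal(sol$k_half, k, tolerance = 1e-9)
    expect_equal(sol$h, h, tolerance = 1e-9)
  }

  expect_error(solve_two_point(50, 0.5, 500, 0.5),
               class = "katharoseq_error_degenerate_points")
  expect_error(solve_two_point(50, 0.9, 500, 0.3),
               class = "katharoseq_error_degenerate_points")
  expect_error(solve_two_point(500, 0.2, 50, 0.9),
               class = "katharoseq_error_degenerate_points")
})

test_that("fit recovers noiseless parameters to high relative accuracy", {
  pts <- exact_hill_points(100, h = 1.4, ymax = 0.95)
  fit <- fit_hill(pts, ymax_mode = "free")
  expect_true(fit$converged)
  expect_equal(fit$k_half, 100, tolerance = 1e-6)
  expect_equal(fit$h, 1.4, tolerance = 1e-6)
  expect_equal(fit$ymax, 0.95, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("fit refuses degenerate input instead of inventing a curve", {
  flat <- tibble::tibble(x = c(1, 10, 100), y = c(0.5, 0.5, 0.5))
  fit <- fit_hill(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$k_half))

  expect_error(fit_hill(tibble::tibble(x = c(1, 10), y = c(0.1, 0.9))),
               class = "katharoseq_error_insufficient_points")
  expect_error(fit_hill(tibble::tibble(x = c(1, 10, 100), y = c(0.1, 0.9, 1.2))),
               class = "katharoseq_error_out_of_range")
})

test_that("two-point solver and fixed-ymax fit agree on two exact levels", {
  x <- c(50, 50, 500, 500)
  y <- hill_curve(x, 1, 96.88, 1.377)
  fit <- fit_hill(tibble::tibble(x = x, y = y), ymax_mode = "fixed_1")
  sol <- solve_two_point(50, y[1], 500, y[3])
  expect_equal(fit$k_half, sol$k_half, tolerance = 1e-7)
  expect_equal(fit$h, sol$h, tolerance = 1e-7)
})

test_that("inversion is exact at the half maximum and consistent elsewhere", {
  fit <- fit_with_k(683, h = 1.2)
  expect_true(fit$converged)
  expect_equal(invert_hill(fit, 0.5), 683, tolerance = 1e-9)

  set.seed(9)
  ys <- runif(20, 0.01, 0.99) * fit$ymax
  xs <- invert_hill(fit, ys)
  expect_equal(hill_curve(xs, fit$ymax, fit$k_half, fit$h), ys, tolerance = 1e-9)

  expect_error(invert_hill(fit, fit$ymax), class = "katharoseq_error_out_of_range")
  expect_error(invert_hill(fit, 0), class = "katharoseq_error_out_of_range")
})

test_that("r-squared matches a hand computation and its boundary cases", {
  # 4 points, fit parameters chosen by hand; residuals computed longhand
  pts <- tibble::tibble(x = c(10, 50, 200, 1000),
                        y = c(0.10, 0.35, 0.70, 0.90))
  fit <- fit_with_k(100, h = 1)  # y = x/(x+100)
  pred <- pts$x / (pts$x + 100)
  expected <- 1 - sum((pts$y - pred)^2) / sum((pts$y - mean(pts$y))^2)
  expect_equal(hill_r_squared(pts, fit), expected, tolerance = 1e-6)

  perfect <- tibble::tibble(x = pts$x, y = pred)
  expect_equal(hill_r_squared(perfect, fit), 1, tolerance = 1e-12)

  flat <- tibble::tibble(x = pts$x, y = rep(0.5, 4))
  expect_error(hill_r_squared(flat, fit), class = "katharoseq_error_zero_variance")
})

test_that("binomial weighting is accepted and keeps the noiseless optimum", {
  pts <- exact_hill_points(100, h = 1.4, ymax = 0.95)
  pts$depth <- rep(1000L, nrow(pts))
  fit <- fit_hill(pts, ymax_mode = "free", weights = "binomial")
  expect_true(fit$converged)
  expect_equal(fit$k_half, 100, tolerance = 1e-4)
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_with_k(683, h = 1.2)
  td <- tidy(fit)
  expect_equal(td$term, c("ymax", "k_half", "h"))
  expect_equal(td$estimate[td$term == "k_half"], 683, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$x_variable, "reads")
  rec <- hill_fit_record(fit)
  expect_named(rec, c("ymax", "k_half", "h", "r_squared", "n_points",
                      "x_variable", "ymax_mode", "converged"))
})
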