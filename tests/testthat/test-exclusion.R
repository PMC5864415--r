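test_that("half-max threshold inverts the reads fit and rounds up", {
  fit683 <- fit_with_k(683, h = 1.3)
  expect_equal(threshold_fit_half_max(fit683), 683L)

  fit_frac <- fit_with_k(10.2, h = 1.3, x = c(1, 3, 10, 30, 100, 300))
  expect_equal(threshold_fit_half_max(fit_frac), 11L)

  low <- fit_hill(exact_hill_points(100, h = 1.4, ymax = 0.4),
                  ymax_mode = "free", x_variable = "reads")
  expect_true(low$converged)
  expect_error(threshold_fit_half_max(low),
               class = "katharoseq_error_unreachable_half")

  cells_fit <- fit_with_k(96.88, x_variable = "cells")
  expect_error(threshold_fit_half_max(cells_fit),
               class = "katharoseq_error_wrong_x_variable")
})

test_that("max-input median threshold uses the lower central depth", {
  pts <- points_tibble(c(500, 5000, 5000, 5000),
                       list(900L, 1500L, 1696L, 2200L), metric = "depth")
  expect_equal(threshold_max_input_median(pts), 1696L)

  single <- points_tibble(5000, list(1234L), metric = "depth")
  expect_equal(threshold_max_input_median(single), 1234L)

  even <- points_tibble(c(5000, 5000), list(10L, 20L), metric = "depth")
  expect_equal(threshold_max_input_median(even), 10L)

  expect_error(threshold_max_input_median(points_tibble(numeric(0), list())),
               class = "katharoseq_error_missing_controls")

  # invariant to duplicating the whole control set
  dup <- dplyr::bind_rows(pts, dplyr::mutate(pts, sample_id = paste0(sample_id, "b")))
  expect_equal(threshold_max_input_median(dup), threshold_max_input_median(pts))
})

test_that("exclusion is boundary-inclusive and partitions the samples", {
  m <- matrix(c(100L, 0L, 683L, 0L, 5000L, 0L), nrow = 2,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  tab <- feature_table(m)
  excl <- apply_exclusion(tab, 683, strategy = "fixed")
  dec <- tidy(excl)
  expect_equal(dec$retained, c(FALSE, TRUE, TRUE))  # "at least 683 reads"
  expect_setequal(sample_ids(excl$table), c("b", "c"))
  expect_equal(nrow(dec), 3)

  all_in <- apply_exclusion(tab, 1, strategy = "fixed")
  expect_true(all(tidy(all_in)$retained))

  # retained columns are untouched
  expect_identical(excl$table$counts[, "c"], m[, "c"])
  expect_error(apply_exclusion(tab, 0, strategy = "fixed"),
               class = "katharoseq_error_invalid_threshold")
})

test_that("exclusion is monotone in depth and conserves counts", {
  set.seed(17)
  for (i in 1:5) {
    tab <- random_table(n_feat = 6, n_samp = 8)
    thr <- sample(20:200, 1)
    excl <- apply_exclusion(tab, thr, strategy = "fixed")
    dec <- tidy(excl)
    # if B retained and A deeper than B, A retained
    for (b in which(dec$retained)) {
      expect_true(all(dec$retained[dec$depth >= dec$depth[b]]))
    }
    expect_equal(sum(dec$retained) + sum(!dec$retained), nrow(dec))
    kept <- dec$sample_id[dec$retained]
    expect_identical(colSums(excl$table$counts)[kept],
                     colSums(tab$counts)[kept])
  }
})

test_that("success rates are retained-over-total within the subset", {
  dec <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    depth = c(rep(1000L, 9), 10L),
    threshold = 100, retained = c(rep(TRUE, 9), FALSE), strategy = "fixed")
  expect_equal(success_rate(dec, dec$sample_id), 0.9)
  expect_equal(success_rate(dec, "s10"), 0)
  expect_error(success_rate(dec, character(0)),
               class = "katharoseq_error_empty_subset")
  expect_error(success_rate(dec, "ghost"),
               class = "katharoseq_error_unknown_sample")

  # 16 of 18 500-cell controls above threshold
  dec18 <- tibble::tibble(
    sample_id = sprintf("p%02d", 1:18),
    depth = c(rep(700L, 16), 100L, 50L),
    threshold = 683, retained = c(rep(TRUE, 16), FALSE, FALSE),
    strategy = "fixed")
  expect_equal(success_rate(dec18, dec18$sample_id), 16 / 18)
  expect_equal(round(success_rate(dec18, dec18$sample_id), 3), 0.889)
})

test_that("gel false-negativity counts read-retained libraries without bands", {
  dec <- tibble::tibble(
    sample_id = sprintf("L%02d", 1:72),
    depth = c(rep(2000L, 37), rep(10L, 35)),
    threshold = 683,
    retained = c(rep(TRUE, 37), rep(FALSE, 35)),
    strategy = "fixed")
  bands <- setNames(c(rep(TRUE, 26), rep(FALSE, 46)), dec$sample_id)
  res <- gel_comparison(dec, bands)
  expect_equal(res$n_retained, 37)
  expect_equal(res$false_negativity, 11 / 37)

  all_banded <- setNames(dec$retained, dec$sample_id)
  expect_equal(gel_comparison(dec, all_banded)$false_negativity, 0)

  no_bands <- setNames(rep(FALSE, 72), dec$sample_id)
  expect_equal(gel_comparison(dec, no_bands)$false_negativity, 1)

  expect_error(gel_comparison(dec, bands[-1]),
               class = "katharoseq_error_incomplete_bands")
})

test_that("contamination report carries the background load and flags leakage", {
  cells_fit <- fit_with_k(96.88, x_variable = "cells")

  clean <- generate_study(simulation_params(n_samples = 20, leakage_rate = 0),
                          seed = 5)
  rep0 <- contamination_report(clean$table, clean$design, "g__Bacillus", cells_fit)
  expect_equal(rep0$background_cells, cells_fit$k_half)
  expect_equal(rep0$target_in_samples$max, 0)

  leaky <- generate_study(simulation_params(n_samples = 40, leakage_rate = 0.01),
                          seed = 6)
  rep1 <- contamination_report(leaky$table, leaky$design, "g__Bacillus", cells_fit)
  expect_equal(rep1$target_in_samples$median, 0.01, tolerance = 0.5)
  expect_gt(rep1$target_in_samples$median, 0)
})
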