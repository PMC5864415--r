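# Shared fixture builders; everything is generated in code.

toy_counts <- function() {
  matrix(c(906L, 94L, 0L,
           0L, 50L, 50L),
         nrow = 3,
         dimnames = list(c("bsub_1", "contam_1", "contam_2"), c("s1", "s2")))
}

toy_taxonomy <- function() {
  c(bsub_1 = "k__Bacteria; g__Bacillus; s__subtilis",
    contam_1 = "k__Bacteria; g__Vibrio; s__fischeri",
    contam_2 = "Unassigned")
}

toy_table <- function() {
  feature_table(toy_counts(), taxonomy = toy_taxonomy())
}

# random valid table for property-style round trips
random_table <- function(n_feat = 5, n_samp = 4, with_tax = TRUE) {
  m <- matrix(rpois(n_feat * n_samp, 30), nrow = n_feat,
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  tax <- if (with_tax) {
    setNames(sprintf("k__Bacteria; g__Genus%02d", seq_len(n_feat)),
             rownames(m))
  } else {
    NULL
  }
  feature_table(m, taxonomy = tax)
}

toy_design <- function() {
  study_design(tibble::tibble(
    sample_id = c("s1", "s2"),
    control_class = c("extraction_positive", "extraction_negative"),
    input_cells = c(500, NA),
    target_spec = c("g__Bacillus", NA)
  ))
}

# design + table for a titration with arbitrary per-level depths/fractions
points_tibble <- function(levels, values, metric = "target_fraction") {
  tibble::tibble(
    sample_id = sprintf("p%03d", seq_along(unlist(values))),
    control_class = "extraction_positive",
    input_cells = rep(levels, lengths(values)),
    depth = if (metric == "depth") unlist(values) else 1000L,
    target_fraction = if (metric == "target_fraction") unlist(values) else 0.5
  )
}

negatives_tibble <- function(values, metric = "target_fraction") {
  tibble::tibble(
    sample_id = sprintf("n%03d", seq_along(values)),
    control_class = "extraction_negative",
    input_cells = NA_real_,
    depth = if (metric == "depth") values else 1000L,
    target_fraction = if (metric == "target_fraction") values else 0
  )
}

# exact Hill points for constructing converged fits with known parameters
exact_hill_points <- function(k_half, h = 1.4, ymax = 1,
                              x = c(5, 20, 50, 100, 200, 500, 2000, 5000)) {
  tibble::tibble(x = x, y = ymax * (x / k_half)^h / (1 + (x / k_half)^h))
}

fit_with_k <- function(k_half, h = 1.4, x_variable = "reads",
                       ymax_mode = "fixed_1",
                       x = c(5, 20, 50, 100, 200, 500, 2000, 5000)) {
  fit_hill(exact_hill_points(k_half, h = h, x = x), ymax_mode = ymax_mode,
           x_variable = x_variable)
}
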