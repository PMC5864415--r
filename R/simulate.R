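#' Parameters of a synthetic titration experiment
#'
#' Defaults describe a realistic low-biomass titration: positive controls at
#' 5, 50, 500 and 5,000 cells with 18 replicates per level, 24 negative
#' controls, a background contamination load of 96.88 cell equivalents with
#' Hill coefficient 1.377, read depth coupled to input biomass through a
#' saturating mean with log-normal noise (median 2,000 reads at the top
#' level, 150 in negatives), and a contaminant background community drawn
#' from a symmetric Dirichlet.
#'
#' @param titration_levels Cell inputs of the positive controls.
#' @param replicates_per_level Positive-control replicates per level.
#' @param n_negatives Number of negative controls (split between extraction
#'   negatives and blanks).
#' @param n_samples Number of true samples (used by [generate_study()]).
#' @param true_k_half,true_h,true_ymax Hill parameters of the
#'   cells-vs-composition relationship the controls obey.
#' @param depth_median_max Median read depth at the largest titration level.
#' @param depth_median_negative Median read depth of negative controls.
#' @param depth_sigma SD of the log-scale multiplicative depth noise.
#' @param depth_k,depth_h Hill parameters of the depth-vs-cells coupling
#'   (`depth_k = NULL` reuses `true_k_half`; `depth_h = 1` is hyperbolic).
#' @param background_taxa Number of contaminant background features.
#' @param background_concentration Symmetric Dirichlet concentration of the
#'   background community (small values give a few dominating contaminants).
#' @param leakage_rate Probability that a read in a non-spiked well is the
#'   target organism (well-to-well leakage); 0 disables leakage.
#' @param sample_cells_range Biomass range (cells) spanned log-uniformly by
#'   true samples, chosen to straddle the background load so some samples
#'   fall below any sensible threshold.
#' @param seed Default seed recorded in the parameters (a seed passed to the
#'   generators takes precedence).
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(titration_levels = c(5, 50, 500, 5000),
                              replicates_per_level = 18,
                              n_negatives = 24,
                              n_samples = 60,
                              true_k_half = 96.88,
                              true_h = 1.377,
                              true_ymax = 1.0,
                              depth_median_max = 2000,
                              depth_median_negative = 150,
                              depth_sigma = 0.5,
                              depth_k = NULL,
                              depth_h = 1,
                              background_taxa = 50,
                              background_concentration = 0.5,
                              leakage_rate = 0,
                              sample_cells_range = c(1, 10000),
                              seed = 1L) {
  p <- list(titration_levels = sort(unique(titration_levels)),
            replicates_per_level = as.integer(replicates_per_level),
            n_negatives = as.integer(n_negatives),
            n_samples = as.integer(n_samples),
            true_k_half = true_k_half, true_h = true_h, true_ymax = true_ymax,
            depth_median_max = depth_median_max,
            depth_median_negative = depth_median_negative,
            depth_sigma = depth_sigma,
            depth_k = depth_k %||% true_k_half, depth_h = depth_h,
            background_taxa = as.integer(background_taxa),
            background_concentration = background_concentration,
            leakage_rate = leakage_rate,
            sample_cells_range = sample_cells_range,
            seed = as.integer(seed))
  ok <- all(p$titration_levels > 0) && p$replicates_per_level > 0 &&
    p$n_negatives >= 0 && p$n_samples >= 0 &&
    p$true_k_half > 0 && p$true_h > 0 && p$true_ymax > 0 && p$true_ymax <= 1 &&
    p$depth_median_max > p$depth_median_negative &&
    p$depth_median_negative >= 0 && p$depth_sigma >= 0 &&
    p$depth_k > 0 && p$depth_h > 0 && p$background_taxa > 0 &&
    p$background_concentration > 0 &&
    p$leakage_rate >= 0 && p$leakage_rate < 1 &&
    length(p$sample_cells_range) == 2 && all(p$sample_cells_range > 0)
  if (!ok) {
    ks_abort("Invalid simulation parameters.", "invalid_params")
  }
  structure(p, class = "simulation_params")
}

TARGET_FEATURE_ID <- "target_bsubtilis"
TARGET_LINEAGE <- "k__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Bacillaceae; g__Bacillus; s__subtilis"

# Saturating depth-biomass coupling: baseline depth of negatives plus a
# Hill-shaped increase, scaled so the median depth at the largest titration
# level equals depth_median_max (log-normal noise has median 1).
depth_mean <- function(cells, params) {
  cmax <- max(params$titration_levels)
  top <- hill_curve(cmax, 1, params$depth_k, params$depth_h)
  params$depth_median_negative +
    (params$depth_median_max - params$depth_median_negative) *
    hill_curve(cells, 1, params$depth_k, params$depth_h) / top
}

# One well: depth, then an exact split of depth into target reads
# (binomial) and a Dirichlet-multinomial background community.
simulate_well <- function(cells, p_target, params) {
  mu <- depth_mean(cells, params)
  depth <- max(0L, as.integer(round(mu * exp(rnorm(1, 0, params$depth_sigma)))))
  target <- if (depth > 0 && p_target > 0) rbinom(1, depth, p_target) else 0L
  n_bg <- depth - target
  bg <- integer(params$background_taxa)
  if (n_bg > 0) {
    w <- rgamma(params$background_taxa, shape = params$background_concentration)
    if (sum(w) == 0) w <- rep(1, params$background_taxa)
    bg <- as.integer(rmultinom(1, n_bg, w / sum(w)))
  }
  c(as.integer(target), bg)
}

assemble_simulation <- function(wells, params, seed) {
  counts <- vapply(wells, `[[`, integer(params$background_taxa + 1L), "counts")
  feature_ids <- c(TARGET_FEATURE_ID,
                   sprintf("bg_%03d", seq_len(params$background_taxa)))
  rownames(counts) <- feature_ids
  colnames(counts) <- vapply(wells, `[[`, character(1), "sample_id")
  taxonomy <- c(
    setNames(TARGET_LINEAGE, TARGET_FEATURE_ID),
    setNames(sprintf("k__Bacteria; g__Contaminant_%03d",
                     seq_len(params$background_taxa)),
             feature_ids[-1])
  )
  n <- length(wells)
  design <- study_design(tibble(
    sample_id = colnames(counts),
    control_class = vapply(wells, `[[`, character(1), "control_class"),
    input_cells = vapply(wells, `[[`, numeric(1), "input_cells"),
    target_spec = ifelse(vapply(wells, `[[`, character(1), "control_class")
                         %in% POSITIVE_CLASSES, "g__Bacillus", NA_character_),
    plate = sprintf("plate%d", (seq_len(n) - 1) %/% 96 + 1),
    well = sprintf("%s%d", LETTERS[(seq_len(n) - 1) %% 8 + 1],
                   ((seq_len(n) - 1) %/% 8) %% 12 + 1)
  ))
  structure(list(table = feature_table(counts, taxonomy = taxonomy),
                 design = design, params = params, seed = seed),
            class = "katharo_simulation")
}

#' Simulate a control titration experiment
#'
#' Generates a feature table and study design emulating a positive-control
#' titration with negative controls: per control at `c` cells, read depth
#' follows a saturating function of `c` with multiplicative log-normal
#' noise, target reads are `Binomial(depth, hill_curve(c))` under the true
#' Hill parameters, and the remaining reads are spread over contaminant
#' background taxa by a Dirichlet-multinomial. Negative controls have zero
#' input cells (target reads only through `leakage_rate`). Deterministic for
#' a fixed seed.
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A `katharo_simulation`: `$table`, `$design`, `$params`, `$seed`.
#' @export
generate_titration <- function(params = simulation_params(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- seed %||% params$seed
  with_rng_seed(seed, {
    assemble_simulation(titration_wells(params), params, seed)
  })
}

titration_wells <- function(params) {
  wells <- list()
  for (c_in in params$titration_levels) {
    p_t <- hill_curve(c_in, params$true_ymax, params$true_k_half, params$true_h)
    for (i in seq_len(params$replicates_per_level)) {
      wells[[length(wells) + 1L]] <- list(
        sample_id = sprintf("pos.%g.%02d", c_in, i),
        control_class = "extraction_positive", input_cells = c_in,
        counts = simulate_well(c_in, p_t, params)
      )
    }
  }
  n_extneg <- ceiling(params$n_negatives / 2)
  for (i in seq_len(params$n_negatives)) {
    cls <- if (i <= n_extneg) "extraction_negative" else "blank"
    id <- if (i <= n_extneg) sprintf("neg.%02d", i)
          else sprintf("blank.%02d", i - n_extneg)
    wells[[length(wells) + 1L]] <- list(
      sample_id = id, control_class = cls, input_cells = NA_real_,
      counts = simulate_well(0, params$leakage_rate, params)
    )
  }
  wells
}

#' Simulate a full low-biomass study
#'
#' [generate_titration()] plus `n_samples` true samples whose biomass spans
#' `sample_cells_range` log-uniformly, so some fall below any read-count
#' threshold a control-based QC would set. True samples carry their own
#' background community; target reads appear in them (and in negatives)
#' only through `leakage_rate`.
#'
#' @inheritParams generate_titration
#' @return A `katharo_simulation`.
#' @export
generate_study <- function(params = simulation_params(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- seed %||% params$seed
  with_rng_seed(seed, {
    wells <- titration_wells(params)
    lr <- log(params$sample_cells_range)
    for (i in seq_len(params$n_samples)) {
      biomass <- exp(runif(1, lr[1], lr[2]))
      wells[[length(wells) + 1L]] <- list(
        sample_id = sprintf("samp.%02d", i),
        control_class = "sample", input_cells = NA_real_,
        counts = simulate_well(biomass, params$leakage_rate, params)
      )
    }
    assemble_simulation(wells, params, seed)
  })
}

#' @export
print.katharo_simulation <- function(x, ...) {
  cat(sprintf("<katharo_simulation> seed %d: %d features x %d samples\n",
              x$seed, nrow(x$table$counts), ncol(x$table$counts)))
  print(table(x$design$control_class))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the same formats the readers consume — a feature table, a TSV
#' sample map — plus a manifest JSON recording every parameter and the seed.
#'
#' @param sim A `katharo_simulation`.
#' @param dir Output directory (created if needed).
#' @param format Feature-table format, `"tsv"` or `"biom"`.
#' @return Named list of written paths, invisibly.
#' @export
write_simulated_study <- function(sim, dir, format = c("tsv", "biom")) {
  stopifnot(inherits(sim, "katharo_simulation"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- file.path(dir, paste0("feature_table.", format))
  met <- file.path(dir, "metadata.tsv")
  man <- file.path(dir, "manifest.json")
  write_feature_table(sim$table, tab, format = format)
  write_metadata(sim$design, met)
  manifest <- c(unclass(sim$params), list(seed_used = sim$seed))
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(table = tab, metadata = met, manifest = man))
}
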