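# Synthetic ddPCR data generator.
#
# Emulates the statistical structure the pipeline assumes, from per-cell
# integer vector copies down to binomial droplet partitioning: true copies
# are drawn from a transduction model, each cell yields up to six
# vector/reference (VG/RG) abundance measurements with multiplicative
# lognormal noise, and each abundance is realised as positive/negative
# droplet counts under Poisson loading. Everything downstream of the seed is
# deterministic, so the generator doubles as the ground truth for
# parameter-recovery studies.

#' Simulation configuration
#'
#' Assembles and validates the parameters of a synthetic ddPCR experiment.
#'
#' @param seed integer seed; fully determines all outputs.
#' @param n_cells number of isolated single cells.
#' @param copy_model one of `"fixed_list"`, `"poisson_moi"`,
#'   `"zero_truncated_poisson"`, `"empirical_weights"`.
#' @param copy_params model parameters: `copies` (fixed_list),
#'   `mean_copies` (the Poisson rate, for the Poisson models), or `weights`
#'   (probabilities over copies `0:(length-1)`).
#' @param sorted_population if `TRUE`, condition on at least one copy
#'   (emulates sorting transduced cells before capture).
#' @param n_combinations VG/RG measurements per cell (default 6: three vector
#'   assays crossed with two reference assays).
#' @param measurement_cv multiplicative lognormal CV applied independently to
#'   each vector and reference abundance.
#' @param preamp_bias_cv CV of a per-(cell, target) multiplicative
#'   preamplification factor; 0 means perfectly linear preamplification.
#'   Large values emulate whole-genome-amplification-style bias.
#' @param droplets_per_well accepted droplets per well.
#' @param droplet_volume_uL droplet volume.
#' @param reference_lambda mean reference-target copies per droplet at the
#'   assay's working dilution; the vector target scales with true copies
#'   relative to the diploid reference.
#' @param reference_copies_per_cell reference-gene copies per genome
#'   (diploid: 2).
#' @param n_chips number of microfluidic chips; cells are allocated
#'   round-robin so chips are exchangeable subsamples by construction.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cells = 80L,
                              copy_model = c("poisson_moi", "fixed_list",
                                             "zero_truncated_poisson",
                                             "empirical_weights"),
                              copy_params = list(mean_copies = 2),
                              sorted_population = FALSE,
                              n_combinations = 6L,
                              measurement_cv = 0.10,
                              preamp_bias_cv = 0,
                              droplets_per_well = 15000L,
                              droplet_volume_uL = 0.00085,
                              reference_lambda = 0.2,
                              reference_copies_per_cell = 2L,
                              n_chips = 1L) {
  copy_model <- match.arg(copy_model)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    vcn_error("seed must be a single integer", "vcn_config_error")
  }
  if (n_cells < 1) vcn_error("n_cells must be >= 1", "vcn_config_error")
  if (measurement_cv < 0) vcn_error("measurement_cv must be >= 0", "vcn_config_error")
  if (droplets_per_well <= 0) vcn_error("droplets_per_well must be > 0", "vcn_config_error")
  if (reference_lambda <= 0) vcn_error("reference_lambda must be > 0", "vcn_config_error")
  if (copy_model == "fixed_list" && is.null(copy_params$copies)) {
    vcn_error("fixed_list requires copy_params$copies", "vcn_config_error")
  }
  if (copy_model %in% c("poisson_moi", "zero_truncated_poisson") &&
      (is.null(copy_params$mean_copies) || copy_params$mean_copies <= 0)) {
    vcn_error("Poisson copy models require copy_params$mean_copies > 0",
              "vcn_config_error")
  }
  if (copy_model == "empirical_weights" &&
      (is.null(copy_params$weights) || any(copy_params$weights < 0) ||
         sum(copy_params$weights) <= 0)) {
    vcn_error("empirical_weights requires non-negative copy_params$weights",
              "vcn_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_cells = as.integer(n_cells),
         copy_model = copy_model, copy_params = copy_params,
         sorted_population = isTRUE(sorted_population),
         n_combinations = as.integer(n_combinations),
         measurement_cv = measurement_cv, preamp_bias_cv = preamp_bias_cv,
         droplets_per_well = as.integer(droplets_per_well),
         droplet_volume_uL = droplet_volume_uL,
         reference_lambda = reference_lambda,
         reference_copies_per_cell = as.integer(reference_copies_per_cell),
         n_chips = as.integer(n_chips)),
    class = "sim_config"
  )
}

#' Poisson rate giving a target zero-truncated mean
#'
#' The mean of a zero-truncated Poisson is \eqn{\lambda / (1 - e^{-\lambda})},
#' which is at least 1; this inverts the relation numerically so populations
#' can be simulated at a prescribed true mean copy number.
#'
#' @param target_mean desired mean of the truncated distribution (>= 1).
#' @return the Poisson rate `lambda`.
#' @export
ztp_rate_for_mean <- function(target_mean) {
  if (target_mean < 1) {
    vcn_error("a zero-truncated Poisson mean cannot be below 1", "vcn_invalid_input")
  }
  if (target_mean <= 1 + 1e-9) return(1e-6)  # degenerate: essentially all ones
  stats::uniroot(function(l) l / (1 - exp(-l)) - target_mean,
                 c(1e-6, 100), tol = 1e-10)$root
}

# zero-truncated Poisson sampler via inverse-CDF conditioning on X >= 1
rztpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(n, p0, 1)
  stats::qpois(u, lambda)
}

#' Draw true per-cell copy numbers
#'
#' Samples each cell's true integer vector copy number from the configured
#' transduction model. `poisson_moi` draws from Poisson(mean_copies) —
#' zero-truncated when `sorted_population` is set; `zero_truncated_poisson`
#' is always truncated at zero.
#'
#' Sets the RNG from `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list of class `synthetic_truth`: `cells` (data.frame `cell_id`,
#'   `chip_id`, `true_copies`) and `realized_pvcn` (mean of the true
#'   copies).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  copies <- switch(config$copy_model,
    fixed_list = {
      k <- config$copy_params$copies
      if (length(k) != n) k <- rep_len(k, n)
      as.integer(k)
    },
    poisson_moi = {
      lam <- config$copy_params$mean_copies
      if (config$sorted_population) rztpois(n, lam) else stats::rpois(n, lam)
    },
    zero_truncated_poisson = rztpois(n, config$copy_params$mean_copies),
    empirical_weights = {
      w <- config$copy_params$weights
      sample(seq_along(w) - 1L, n, replace = TRUE, prob = w / sum(w))
    }
  )
  cells <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n)),
    chip_id = sprintf("chip%d", ((seq_len(n) - 1L) %% config$n_chips) + 1L),
    true_copies = as.integer(copies),
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, realized_pvcn = mean(cells$true_copies)),
            class = "synthetic_truth")
}

# lognormal multiplicative factor with mean exactly 1 and the given CV
rlnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

default_combinations <- function(n_combinations) {
  vg <- paste0("VG", 1:3)
  rg <- paste0("RG", 1:2)
  combos <- expand.grid(vg = vg, rg = rg, stringsAsFactors = FALSE)
  combos <- combos[order(combos$vg, combos$rg), , drop = FALSE]
  utils::head(combos, n_combinations)
}

#' Simulate per-cell VG/RG abundance measurements
#'
#' For each cell and assay combination, the vector-target occupancy is
#' `reference_lambda x true_copies / reference_copies_per_cell`, and the
#' reference-target occupancy is `reference_lambda`; each gets an
#' independent lognormal(mean 1, `measurement_cv`) factor, plus an optional
#' per-(cell, target) preamplification-bias factor. Cells with zero copies
#' produce exactly zero vector signal.
#'
#' Continues the RNG stream started by [simulate_cells()].
#'
#' @param truth a `synthetic_truth`.
#' @param config the `sim_config` used to generate `truth`.
#' @return long data.frame: `cell_id`, `chip_id`, `combination_id`,
#'   `vg_target`, `rg_target`, `vg_lambda`, `rg_lambda`, `measured_vcn`
#'   (the noisy abundance ratio before droplet sampling).
#' @export
simulate_measurements <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  combos <- default_combinations(config$n_combinations)
  cells <- truth$cells
  n <- nrow(cells)
  nc <- nrow(combos)

  # per-(cell, target) preamplification factors, shared across combinations
  targets <- unique(c(combos$vg, combos$rg))
  bias <- matrix(rlnorm_mean1(n * length(targets), config$preamp_bias_cv),
                 nrow = n, dimnames = list(cells$cell_id, targets))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    vg_noise <- rlnorm_mean1(nc, config$measurement_cv)
    rg_noise <- rlnorm_mean1(nc, config$measurement_cv)
    vg_lambda <- config$reference_lambda * cells$true_copies[i] /
      config$reference_copies_per_cell *
      vg_noise * bias[i, combos$vg]
    rg_lambda <- config$reference_lambda * rg_noise * bias[i, combos$rg]
    out[[i]] <- data.frame(
      cell_id = cells$cell_id[i],
      chip_id = cells$chip_id[i],
      combination_id = paste(combos$vg, combos$rg, sep = "/"),
      vg_target = combos$vg, rg_target = combos$rg,
      vg_lambda = vg_lambda, rg_lambda = rg_lambda,
      measured_vcn = config$reference_copies_per_cell * vg_lambda / rg_lambda,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Realise abundances as droplet counts
#'
#' Each droplet is positive for a target independently with probability
#' `1 - exp(-lambda)`, the Poisson partitioning the ddPCR readout inverts.
#' Emits well records in the dialect the [read_wells()] reader consumes:
#' one duplex well per (cell, combination), two target rows per well.
#'
#' Continues the RNG stream.
#'
#' @param abundances output of [simulate_measurements()] (or any data.frame
#'   with `cell_id`, `chip_id`, `combination_id`, `vg_target`, `rg_target`,
#'   `vg_lambda`, `rg_lambda`).
#' @param config the `sim_config`.
#' @param sample_kind recorded in the layout; `"single_cell"` or
#'   `"bulk_gdna"`.
#' @return list with `wells` (per-target droplet rows) and `layout`
#'   (per-well sample mapping).
#' @export
simulate_droplets <- function(abundances, config, sample_kind = "single_cell") {
  stopifnot(inherits(config, "sim_config"))
  nt <- config$droplets_per_well
  n <- nrow(abundances)
  well_id <- sprintf("%s_w%02d", abundances$cell_id,
                     stats::ave(seq_len(n), abundances$cell_id, FUN = seq_along))
  draw <- function(lambda) {
    stats::rbinom(length(lambda), nt, 1 - exp(-pmax(lambda, 0)))
  }
  wells <- rbind(
    data.frame(well_id = well_id, sample_id = abundances$cell_id,
               chip_id = abundances$chip_id,
               target_name = abundances$vg_target, target_role = "vector",
               n_positive = draw(abundances$vg_lambda), n_total = nt,
               stringsAsFactors = FALSE),
    data.frame(well_id = well_id, sample_id = abundances$cell_id,
               chip_id = abundances$chip_id,
               target_name = abundances$rg_target, target_role = "reference",
               n_positive = draw(abundances$rg_lambda), n_total = nt,
               stringsAsFactors = FALSE)
  )
  wells <- wells[order(wells$well_id, wells$target_role, decreasing = c(FALSE, TRUE),
                       method = "radix"), , drop = FALSE]
  rownames(wells) <- NULL
  layout <- data.frame(
    well_id = well_id, sample_id = abundances$cell_id,
    sample_kind = sample_kind, chip_id = abundances$chip_id,
    stringsAsFactors = FALSE
  )
  list(wells = wells, layout = layout)
}

# bulk gDNA wells for the realized population: one well per combination,
# vector occupancy proportional to the population mean copy number
simulate_bulk_wells <- function(truth, config, sample_id = "bulk1") {
  combos <- default_combinations(config$n_combinations)
  nc <- nrow(combos)
  vg_noise <- rlnorm_mean1(nc, config$measurement_cv)
  rg_noise <- rlnorm_mean1(nc, config$measurement_cv)
  ab <- data.frame(
    cell_id = sample_id, chip_id = NA_character_,
    combination_id = paste(combos$vg, combos$rg, sep = "/"),
    vg_target = combos$vg, rg_target = combos$rg,
    vg_lambda = config$reference_lambda * truth$realized_pvcn /
      config$reference_copies_per_cell * vg_noise,
    rg_lambda = config$reference_lambda * rg_noise,
    stringsAsFactors = FALSE
  )
  simulate_droplets(ab, config, sample_kind = "bulk_gdna")
}

#' Generate a complete synthetic dataset in memory
#'
#' Runs [simulate_cells()], [simulate_measurements()], [simulate_droplets()]
#' and a bulk-gDNA companion sample under one seed.
#'
#' @param config a `sim_config`.
#' @param include_bulk also simulate a bulk gDNA sample of the same
#'   population.
#' @return list with `truth`, `measurements` (pre-droplet abundances),
#'   `wells`, `layout`, `config`.
#' @export
simulate_dataset <- function(config, include_bulk = TRUE) {
  truth <- simulate_cells(config)
  measurements <- simulate_measurements(truth, config)
  sc <- simulate_droplets(measurements, config)
  wells <- sc$wells
  layout <- sc$layout
  if (include_bulk) {
    bulk <- simulate_bulk_wells(truth, config)
    wells <- rbind(wells, bulk$wells)
    layout <- rbind(layout, bulk$layout)
  }
  list(truth = truth, measurements = measurements,
       wells = wells, layout = layout, config = config)
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes `wells.csv`, `layout.csv`, `truth.json` and `config.json` into
#' `dir`, byte-identical for a given seed.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @param include_bulk include a bulk gDNA companion sample.
#' @return invisibly, the named paths written.
#' @export
make_fixture_bundle <- function(config, dir, include_bulk = TRUE) {
  ds <- simulate_dataset(config, include_bulk = include_bulk)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    wells = file.path(dir, "wells.csv"),
    layout = file.path(dir, "layout.csv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  utils::write.csv(ds$wells, paths[["wells"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$layout, paths[["layout"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(cells = ds$truth$cells, realized_pvcn = ds$truth$realized_pvcn),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
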