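# Independent brute-force oracles and small fixture builders shared across
# tests. The oracle deliberately re-derives the model from the density
# definitions (stats::dnorm) rather than calling the package's likelihood
# code, so agreement is a real cross-check.

oracle_transform <- function(x, transform) {
  switch(transform, sqrt = sqrt(x), log1p = log1p(x), identity = x)
}

# log prior x likelihood over the support, cell-mean aggregation
oracle_log_weights <- function(values, sigma, support, transform = "sqrt",
                               prior = NULL) {
  y <- oracle_transform(mean(values), transform)
  se <- sigma / sqrt(length(values))
  if (is.null(prior)) prior <- rep(1 / length(support), length(support))
  ll <- vapply(support, function(k) {
    if (k == 0) log(2) + dnorm(abs(y), 0, se, log = TRUE)
    else dnorm(y, oracle_transform(k, transform), se, log = TRUE)
  }, numeric(1))
  log(prior) + ll
}

oracle_map <- function(values, sigma, support, transform = "sqrt", prior = NULL) {
  w <- oracle_log_weights(values, sigma, support, transform, prior)
  support[which.max(w)]  # first maximum = smallest copy on a sorted support
}

oracle_posterior <- function(values, sigma, support, transform = "sqrt",
                             prior = NULL) {
  w <- oracle_log_weights(values, sigma, support, transform, prior)
  p <- exp(w - max(w))
  p / sum(p)
}

# long measurement table (cell_id, chip_id, combination_id, vcn) from a
# simulated abundance table, the shape infer_dataset() consumes
measurements_table <- function(abundances) {
  data.frame(cell_id = abundances$cell_id,
             chip_id = abundances$chip_id,
             combination_id = abundances$combination_id,
             vcn = abundances$measured_vcn,
             stringsAsFactors = FALSE)
}

# simulate true copies + noisy measurements and return everything needed for
# a recovery check
simulate_recovery_data <- function(seed, n_cells, copy_model, copy_params,
                                   measurement_cv, n_chips = 1) {
  cfg <- simulation_config(seed = seed, n_cells = n_cells,
                           copy_model = copy_model, copy_params = copy_params,
                           measurement_cv = measurement_cv, n_chips = n_chips)
  truth <- simulate_cells(cfg)
  meas <- simulate_measurements(truth, cfg)
  list(config = cfg, truth = truth, measurements = measurements_table(meas))
}

# one droplet-well row in the canonical reader dialect
make_well <- function(well_id = "A01", sample_id = "s1", target_name = "VG1",
                      target_role = "vector", n_positive = 500,
                      n_total = 15000, chip_id = NA_character_, ...) {
  data.frame(well_id = well_id, sample_id = sample_id, chip_id = chip_id,
             target_name = target_name, target_role = target_role,
             n_positive = n_positive, n_total = n_total, ...,
             stringsAsFactors = FALSE)
}
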