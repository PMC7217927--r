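# Bayesian inference of integer vector copy number per single cell.
#
# Model: after a variance-stabilizing transform T, a cell's VCN measurement
# is the transformed true copy number plus zero-mean Gaussian noise with a
# constant, dataset-level standard deviation sigma. For each candidate
# integer copy k the likelihood of the cell's summary statistic is a normal
# density centred at T(k) (k > 0) or a half-normal density at the origin
# (k = 0, absolute errors: a cell cannot show negative signal). A uniform
# prior over the dataset's candidate copies makes the maximum a posteriori
# call coincide with the maximum-likelihood call.

#' Build per-cell measurement sets from a long measurement table
#'
#' Collapses a long table of per-combination VCN measurements into one row
#' per cell with validity counts and the mean/SEM over non-missing values.
#'
#' @param measurements data.frame with columns `cell_id`, `combination_id`,
#'   `vcn` (NA for quality-filtered data points) and optionally `chip_id`.
#' @param n_combinations number of measurements attempted per cell; missing
#'   rows count as NAs toward this total.
#' @return data.frame with `cell_id`, `chip_id`, `n_valid`, `n_missing`,
#'   `mean_vcn`, `sem_vcn`.
#' @export
cell_measurements <- function(measurements, n_combinations = 6) {
  stopifnot(is.data.frame(measurements),
            all(c("cell_id", "vcn") %in% names(measurements)))
  if (!"chip_id" %in% names(measurements)) measurements$chip_id <- NA_character_
  out <- do.call(rbind, lapply(split(measurements, measurements$cell_id), function(d) {
    x <- d$vcn[!is.na(d$vcn)]
    nv <- length(x)
    data.frame(
      cell_id = d$cell_id[1],
      chip_id = d$chip_id[1],
      n_valid = nv,
      n_missing = max(n_combinations - nv, 0L),
      mean_vcn = if (nv > 0) mean(x) else NA_real_,
      sem_vcn = if (nv > 1) stats::sd(x) / sqrt(nv) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Remove cells with too many missing measurements
#'
#' A cell is retained only when it has at most `max_missing` NA measurements
#' out of the attempted set (default: more than 3 NAs out of 6 removes the
#' cell, so a cell with exactly 3 NAs is kept).
#'
#' @param cells per-cell data.frame from [cell_measurements()].
#' @param max_missing maximum tolerated NA count.
#' @return the retained subset of `cells`.
#' @export
filter_cells <- function(cells, max_missing = 3) {
  stopifnot(is.data.frame(cells), "n_missing" %in% names(cells))
  cells[cells$n_missing <= max_missing, , drop = FALSE]
}

#' Estimate the dataset-level measurement noise
#'
#' Pools the within-cell scatter of transformed VCN measurements into one
#' constant standard deviation:
#' \deqn{\sigma^2 = \frac{\sum_c \sum_j (T(y_{cj}) - \bar{T(y_c)})^2}{\sum_c (m_c - 1)}}
#' over cells with at least two valid measurements. The constant-variance
#' assumption is what the variance-stabilizing transform buys; replicate
#' scatter is treated as independent of the copy number.
#'
#' @param measurements long data.frame (`cell_id`, `vcn`), already restricted
#'   to retained cells.
#' @param transform variance-stabilizing transform name (see
#'   [vcn_transform()]).
#' @param sigma_floor lower clip for sigma; degenerate no-noise input would
#'   otherwise produce point-mass likelihoods.
#' @param min_cells below this many contributing cells the estimate is
#'   considered unreliable and `default_sigma` is used (with a warning).
#' @param default_sigma fallback sigma on the transformed scale.
#' @return object of class `vcn_noise_model`: list with `transform`, `sigma`,
#'   `estimation_n` (measurement pairs used) and `n_cells`.
#' @export
estimate_noise <- function(measurements, transform = c("sqrt", "log1p", "identity"),
                           sigma_floor = 1e-3, min_cells = 5, default_sigma = 0.1) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(measurements),
            all(c("cell_id", "vcn") %in% names(measurements)))
  ss <- 0
  df <- 0L
  n_cells <- 0L
  n_obs <- 0L
  for (d in split(measurements, measurements$cell_id)) {
    y <- vcn_transform(d$vcn[!is.na(d$vcn)], transform)
    if (length(y) < 2) next
    ss <- ss + sum((y - mean(y))^2)
    df <- df + length(y) - 1L
    n_cells <- n_cells + 1L
    n_obs <- n_obs + length(y)
  }
  if (n_cells < min_cells) {
    vcn_warn(sprintf(
      "only %d cells with >= 2 valid measurements; falling back to default sigma %.4g",
      n_cells, default_sigma), "vcn_sigma_fallback")
    sigma <- default_sigma
  } else {
    sigma <- sqrt(ss / df)
  }
  sigma <- max(sigma, sigma_floor)
  structure(
    list(transform = transform, sigma = sigma,
         estimation_n = n_obs, n_cells = n_cells),
    class = "vcn_noise_model"
  )
}

#' @export
print.vcn_noise_model <- function(x, ...) {
  cat(sprintf("VCN noise model: sigma = %.4g on the %s scale (%d measurements from %d cells)\n",
              x$sigma, x$transform, x$estimation_n, x$n_cells))
  invisible(x)
}

#' Likelihood of a candidate copy number
#'
#' Density of the cell's transformed summary statistic under candidate copy
#' `k`: normal with mean `T(k)` and SD `sigma_eff` for `k > 0`; half-normal
#' with scale `sigma_eff` for `k = 0` (absolute errors around zero — the
#' density at the origin is twice the normal peak).
#'
#' @param y_summary transformed per-cell statistic (scalar or vector).
#' @param k candidate copy number, non-negative integer (scalar).
#' @param noise a `vcn_noise_model`.
#' @param n_valid number of measurements behind `y_summary`; the effective
#'   SD is `noise$sigma / sqrt(n_valid)`.
#' @param log return log density?
#' @return (log) likelihood values.
#' @export
copy_likelihood <- function(y_summary, k, noise, n_valid = 1, log = FALSE) {
  if (length(k) != 1 || !is.finite(k) || k < 0 || k != round(k)) {
    vcn_error("k must be a single non-negative integer", "vcn_invalid_input")
  }
  stopifnot(inherits(noise, "vcn_noise_model"))
  sigma_eff <- noise$sigma / sqrt(n_valid)
  if (k == 0) {
    ll <- stats::dnorm(abs(y_summary), mean = 0, sd = sigma_eff, log = TRUE) + log(2)
  } else {
    ll <- stats::dnorm(y_summary, mean = vcn_transform(k, noise$transform),
                       sd = sigma_eff, log = TRUE)
  }
  if (log) ll else exp(ll)
}

#' Infer the posterior over integer copy numbers for one cell
#'
#' Evaluates prior x likelihood over the candidate support in log space,
#' normalises by log-sum-exp, and reports the maximum a posteriori copy.
#' Ties break toward the smaller copy (conservative for a safety-relevant
#' quantity). Under the default uniform prior the MAP call equals the
#' maximum-likelihood call.
#'
#' Two aggregation modes are available for the up-to-six measurements:
#' `"cell_mean"` (default) uses `T(mean(values))` as the summary statistic
#' with effective SD `sigma / sqrt(n_valid)`; `"replicate_sum"` sums the
#' per-replicate log likelihoods at SD `sigma`.
#'
#' @param values the cell's non-missing VCN measurements.
#' @param noise a `vcn_noise_model`.
#' @param support integer candidate copies, typically `0:K_max`.
#' @param prior prior probabilities over `support`; default uniform. Must sum
#'   to 1.
#' @param aggregation `"cell_mean"` or `"replicate_sum"`.
#' @param cell_id,chip_id identifiers carried into the result.
#' @return object of class `copy_posterior`: list with `cell_id`, `chip_id`,
#'   `support`, `prior`, `log_likelihood`, `posterior`, `map_copy`,
#'   `map_prob`, `ml_copy`, `n_valid`, `mean_vcn`.
#' @export
infer_cell <- function(values, noise, support, prior = NULL,
                       aggregation = c("cell_mean", "replicate_sum"),
                       cell_id = NA_character_, chip_id = NA_character_) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(noise, "vcn_noise_model"))
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    vcn_error("infer_cell needs at least one non-missing measurement",
              "vcn_insufficient_data")
  }
  support <- as.integer(support)
  if (any(support < 0) || anyDuplicated(support)) {
    vcn_error("support must be distinct non-negative integers", "vcn_invalid_input")
  }
  if (is.null(prior)) {
    prior <- rep(1 / length(support), length(support))
  }
  if (length(prior) != length(support) || any(prior < 0) ||
      abs(sum(prior) - 1) > 1e-6) {
    vcn_error("prior must be a probability vector over the support",
              "vcn_invalid_input")
  }

  n_valid <- length(values)
  mean_vcn <- mean(values)
  loglik <- vapply(support, function(k) {
    if (aggregation == "cell_mean") {
      y <- vcn_transform(mean_vcn, noise$transform)
      copy_likelihood(y, k, noise, n_valid = n_valid, log = TRUE)
    } else {
      y <- vcn_transform(values, noise$transform)
      sum(copy_likelihood(y, k, noise, n_valid = 1, log = TRUE))
    }
  }, numeric(1))

  log_post <- log(prior) + loglik
  norm <- logsumexp(log_post)
  if (!is.finite(norm)) {
    vcn_error("posterior is degenerate: all likelihoods underflowed",
              "vcn_degenerate_posterior")
  }
  posterior <- exp(log_post - norm)
  # argmax with ties broken toward the smaller copy (support sorted ascending)
  ord <- order(support)
  map_idx <- ord[which.max(posterior[ord])]
  ml_idx <- ord[which.max(loglik[ord])]
  structure(
    list(cell_id = cell_id, chip_id = chip_id,
         support = support, prior = prior,
         log_likelihood = loglik, posterior = posterior,
         map_copy = support[map_idx], map_prob = posterior[map_idx],
         ml_copy = support[ml_idx],
         n_valid = n_valid, mean_vcn = mean_vcn),
    class = "copy_posterior"
  )
}

#' @export
print.copy_posterior <- function(x, ...) {
  cat(sprintf("Cell %s: MAP copy %d (posterior %.3f) from %d measurements, mean VCN %.3f\n",
              x$cell_id, x$map_copy, x$map_prob, x$n_valid, x$mean_vcn))
  invisible(x)
}

#' Candidate copy support for a dataset
#'
#' The prior distributes equal probability over "all possible vector copies
#' in the dataset"; the upper bound is the largest observed per-cell mean,
#' rounded up, plus a margin, never below a minimum:
#' `K_max = max(ceiling(max mean_vcn) + K_margin, K_min)`.
#'
#' @param mean_vcns per-cell mean VCN values.
#' @param K_margin copies added above the observed maximum.
#' @param K_min lower bound on the support maximum.
#' @return integer vector `0:K_max`.
#' @export
copy_support <- function(mean_vcns, K_margin = 2, K_min = 5) {
  mean_vcns <- mean_vcns[is.finite(mean_vcns)]
  k_max <- if (length(mean_vcns) == 0) K_min else
    max(ceiling(max(mean_vcns)) + K_margin, K_min)
  0:as.integer(k_max)
}

#' Run Bayesian copy-number inference over a dataset
#'
#' Orchestrates the per-cell workflow: build measurement sets, drop cells
#' with more than `max_missing` NAs, estimate the noise model (unless
#' `sigma_override` is given), fix the candidate support from the observed
#' per-cell means, and infer each cell's posterior. Deterministic given its
#' inputs.
#'
#' @param measurements long data.frame with `cell_id`, `combination_id`,
#'   `vcn`, optionally `chip_id`.
#' @param transform variance-stabilizing transform.
#' @param aggregation see [infer_cell()].
#' @param n_combinations measurements attempted per cell.
#' @param max_missing NA tolerance per cell.
#' @param sigma_override use this sigma instead of estimating one.
#' @param K_margin,K_min support rule parameters (see [copy_support()]).
#' @param prior optional prior over the support; default uniform.
#' @return list with `cells` (per-cell data.frame: `cell_id`, `chip_id`,
#'   `n_valid`, `mean_vcn`, `sem_vcn`, `map_copy`, `map_prob`, `ml_copy`),
#'   `posteriors` (list of `copy_posterior`), `noise` (the
#'   `vcn_noise_model`), `support`, and `n_filtered` (cells removed by the
#'   NA rule).
#' @export
infer_dataset <- function(measurements,
                          transform = c("sqrt", "log1p", "identity"),
                          aggregation = c("cell_mean", "replicate_sum"),
                          n_combinations = 6, max_missing = 3,
                          sigma_override = NULL, K_margin = 2, K_min = 5,
                          prior = NULL) {
  transform <- match.arg(transform)
  aggregation <- match.arg(aggregation)

  cells <- cell_measurements(measurements, n_combinations = n_combinations)
  retained <- filter_cells(cells, max_missing = max_missing)
  if (nrow(retained) == 0) {
    vcn_error("no cells remain after NA filtering", "vcn_insufficient_data")
  }
  kept_meas <- measurements[measurements$cell_id %in% retained$cell_id, , drop = FALSE]

  noise <- if (is.null(sigma_override)) {
    estimate_noise(kept_meas, transform = transform)
  } else {
    structure(list(transform = transform, sigma = sigma_override,
                   estimation_n = 0L, n_cells = 0L),
              class = "vcn_noise_model")
  }

  support <- copy_support(retained$mean_vcn, K_margin = K_margin, K_min = K_min)

  posteriors <- lapply(seq_len(nrow(retained)), function(i) {
    d <- kept_meas[kept_meas$cell_id == retained$cell_id[i], , drop = FALSE]
    infer_cell(d$vcn, noise, support, prior = prior, aggregation = aggregation,
               cell_id = retained$cell_id[i], chip_id = retained$chip_id[i])
  })

  retained$map_copy <- vapply(posteriors, `[[`, integer(1), "map_copy")
  retained$map_prob <- vapply(posteriors, `[[`, numeric(1), "map_prob")
  retained$ml_copy <- vapply(posteriors, `[[`, integer(1), "ml_copy")

  list(cells = retained, posteriors = posteriors, noise = noise,
       support = support, n_filtered = nrow(cells) - nrow(retained))
}
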