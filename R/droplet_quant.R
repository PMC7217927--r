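# Poisson quantification of droplet digital PCR wells and well-level QC.
#
# ddPCR partitions a reaction into thousands of droplets; end-point PCR
# classifies each droplet positive or negative for a target. Under Poisson
# loading, the fraction of negative droplets is exp(-lambda), where lambda is
# the mean number of target copies per droplet, so lambda is recovered as
# -log(1 - p) with p the positive fraction.

#' Estimate per-droplet target occupancy from droplet counts
#'
#' Inverts the Poisson partitioning model: with `n_positive` positive droplets
#' out of `n_total` accepted droplets, the mean copies per droplet is
#' \eqn{\hat\lambda = -\ln(1 - n_{pos}/n_{tot})}.
#'
#' @param n_positive number of positive droplets (vectorised).
#' @param n_total number of accepted droplets (> 0).
#' @return estimated copies per droplet; `Inf` when every droplet is positive
#'   (the well is saturated and cannot be quantified).
#' @examples
#' estimate_lambda(0, 15000)      # no template
#' estimate_lambda(9482, 15000)   # ~1 copy per droplet
#' @export
estimate_lambda <- function(n_positive, n_total) {
  if (any(!is.finite(n_total)) || any(n_total <= 0)) {
    vcn_error("n_total must be a positive droplet count", "vcn_invalid_input")
  }
  if (any(!is.finite(n_positive)) || any(n_positive < 0) || any(n_positive > n_total)) {
    vcn_error("n_positive must satisfy 0 <= n_positive <= n_total", "vcn_invalid_input")
  }
  p_hat <- n_positive / n_total
  ifelse(p_hat >= 1, Inf, -log1p(-p_hat))
}

#' Well-level quality control
#'
#' Applies the two exclusion rules used for ddPCR wells: a well fails when
#' fewer than `min_droplets` droplets were accepted (default 11,000; a well
#' with exactly 11,000 passes), and optionally when its mean fluorescence
#' amplitude is a robust outlier relative to same-target wells. A well with
#' fewer than `min_negatives` negative droplets is flagged `saturated`:
#' the Poisson inversion is unreliable (or infinite) there, and such wells are
#' excluded from VCN ratios.
#'
#' QC never raises an error and never modifies its input.
#'
#' @param wells data.frame of droplet wells, one row per (well, target), with
#'   at least `n_positive` and `n_total`; `mean_amp_pos` / `mean_amp_neg` and
#'   `target_name` are used by the amplitude rule when present.
#' @param min_droplets minimum accepted droplets for a well to pass.
#' @param min_negatives fewer negative droplets than this flags saturation.
#' @param amplitude_z robust z-score threshold (median/MAD, applied within
#'   `target_name` groups) above which an amplitude is called an outlier; set
#'   `NULL` to disable even when amplitude columns are present.
#' @return `wells` with logical `qc_pass` and character `qc_reasons`
#'   (semicolon-separated, `""` when the well passes) columns appended.
#' @export
qc_well <- function(wells, min_droplets = 11000, min_negatives = 3,
                    amplitude_z = 3.5) {
  stopifnot(is.data.frame(wells), all(c("n_positive", "n_total") %in% names(wells)))
  n <- nrow(wells)
  reasons <- vector("list", n)

  too_few <- wells$n_total < min_droplets
  saturated <- (wells$n_total - wells$n_positive) < min_negatives

  amp_out <- rep(FALSE, n)
  amp_cols <- intersect(c("mean_amp_pos", "mean_amp_neg"), names(wells))
  if (length(amp_cols) > 0 && !is.null(amplitude_z)) {
    grp <- if ("target_name" %in% names(wells)) wells$target_name else rep("all", n)
    for (col in amp_cols) {
      x <- wells[[col]]
      for (g in unique(grp)) {
        idx <- which(grp == g & !is.na(x))
        if (length(idx) < 4) next  # too few wells for a robust spread
        med <- stats::median(x[idx])
        mad <- stats::mad(x[idx])
        if (mad <= 0) next
        amp_out[idx] <- amp_out[idx] | abs(x[idx] - med) / mad > amplitude_z
      }
    }
  }

  for (i in seq_len(n)) {
    r <- character(0)
    if (too_few[i]) r <- c(r, "too_few_droplets")
    if (saturated[i]) r <- c(r, "saturated")
    if (amp_out[i]) r <- c(r, "amplitude_outlier")
    reasons[[i]] <- r
  }
  wells$qc_pass <- lengths(reasons) == 0
  wells$qc_reasons <- vapply(reasons, paste, "", collapse = ";")
  wells
}

#' Quantify droplet wells
#'
#' Combines Poisson occupancy estimation with QC: appends `lambda_hat`
#' (copies/droplet), `concentration` (copies/uL, `lambda_hat` divided by the
#' droplet volume) and the QC columns of [qc_well()].
#'
#' The droplet volume only scales reported concentrations; VCN is a ratio of
#' two concentrations from the same well and is invariant to it. The default
#' is the nominal QX200 droplet volume.
#'
#' @param wells data.frame of droplet wells (see [read_wells()] for the
#'   expected columns).
#' @param droplet_volume_uL droplet volume in microlitres.
#' @inheritParams qc_well
#' @return `wells` with quantification and QC columns appended.
#' @export
quantify_well <- function(wells, droplet_volume_uL = 0.00085,
                          min_droplets = 11000, min_negatives = 3,
                          amplitude_z = 3.5) {
  if (!is.numeric(droplet_volume_uL) || droplet_volume_uL <= 0) {
    vcn_error("droplet_volume_uL must be > 0", "vcn_invalid_input")
  }
  wells <- qc_well(wells, min_droplets = min_droplets,
                   min_negatives = min_negatives, amplitude_z = amplitude_z)
  wells$lambda_hat <- estimate_lambda(wells$n_positive, wells$n_total)
  wells$concentration <- wells$lambda_hat / droplet_volume_uL
  wells
}
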