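# Vector copy number arithmetic: per-measurement VCN, bulk population
# summaries, replicate CVs, and the percent difference between single-cell
# and bulk estimates.

#' Compute vector copy number from paired target abundances
#'
#' VCN per diploid genome is twice the ratio of vector-target to
#' human-reference-target abundance measured in the same reaction:
#' \eqn{VCN = 2 \times vector / reference}. The factor 2 assumes a diploid
#' genome carrying two copies of the reference gene.
#'
#' Failure modes yield `NA` with a machine-readable reason rather than an
#' error, mirroring the per-data-point NA replacement used during quality
#' filtering: a non-positive reference abundance gives `reference_failure`;
#' a QC-failed contributing well gives `qc_fail`.
#'
#' @param vector_conc vector-target abundance (copies/uL); vectorised.
#' @param reference_conc reference-target abundance, same units.
#' @param vector_qc,reference_qc logical QC status of the contributing wells.
#' @return data.frame with columns `vcn` and `na_reason` (`NA_character_`
#'   when the value is present).
#' @export
compute_vcn <- function(vector_conc, reference_conc,
                        vector_qc = TRUE, reference_qc = TRUE) {
  n <- max(length(vector_conc), length(reference_conc))
  vector_conc <- rep_len(vector_conc, n)
  reference_conc <- rep_len(reference_conc, n)
  vector_qc <- rep_len(vector_qc, n)
  reference_qc <- rep_len(reference_qc, n)

  vcn <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  qc_bad <- !vector_qc | !reference_qc
  ref_bad <- !qc_bad & (!is.finite(reference_conc) | reference_conc <= 0 |
                          !is.finite(vector_conc))
  ok <- !qc_bad & !ref_bad
  vcn[ok] <- 2 * vector_conc[ok] / reference_conc[ok]
  reason[qc_bad] <- "qc_fail"
  reason[ref_bad] <- "reference_failure"
  data.frame(vcn = vcn, na_reason = reason, stringsAsFactors = FALSE)
}

#' Summarise a set of bulk VCN measurements
#'
#' Mean, sample standard deviation (n-1 denominator by default) and
#' coefficient of variation over the non-missing replicate VCN values of a
#' bulk genomic DNA sample, typically the six unique vector/reference assay
#' combinations.
#'
#' @param values numeric VCN measurements; `NA`s are dropped.
#' @param sd_type `"sample"` (n-1) or `"population"` (n) denominator.
#' @return list with `pvcn_mean`, `pvcn_sd`, `cv_percent`, `n_measurements`.
#' @export
population_vcn <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    vcn_error("population_vcn needs at least 2 non-missing measurements",
              "vcn_insufficient_data")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  list(
    pvcn_mean = m,
    pvcn_sd = s,
    cv_percent = if (m > 0) 100 * s / m else NA_real_,
    n_measurements = n
  )
}

#' Percent difference between bulk and single-cell VCN
#'
#' \eqn{\Delta VCN = |pVCN - \bar{scVCN}| / pVCN \times 100}, the accuracy
#' proxy comparing the mean of single-cell copy-number predictions to the
#' orthogonal bulk measurement on genomic DNA.
#'
#' @param pvcn bulk population VCN (> 0).
#' @param scvcn_mean mean of the single-cell VCN predictions.
#' @return percent difference.
#' @examples
#' delta_vcn(2.3, 1.9)  # 17.39
#' @export
delta_vcn <- function(pvcn, scvcn_mean) {
  if (any(!is.finite(pvcn)) || any(pvcn <= 0)) {
    vcn_error("pvcn must be > 0", "vcn_invalid_input")
  }
  abs(pvcn - scvcn_mean) / pvcn * 100
}

#' Replicate CV per target and per target group
#'
#' Scores preamplification linearity: for each assay target the coefficient
#' of variation across replicate absolute copy measurements, and the mean CV
#' within each target group (vector genes vs reference genes). A strongly
#' non-uniform CV profile indicates amplification bias that would distort the
#' VCN ratio.
#'
#' @param copies data.frame with columns `target_name`, `target_role`
#'   (`"vector"` / `"reference"`) and `copies` (replicate absolute copies).
#' @return list with `per_target` (target_name, target_role, n, cv_percent;
#'   `NA` when a target has a single replicate) and `group_mean`
#'   (target_role, mean_cv_percent over targets with a defined CV).
#' @export
amplification_bias_cv <- function(copies) {
  stopifnot(is.data.frame(copies),
            all(c("target_name", "target_role", "copies") %in% names(copies)))
  per_target <- do.call(rbind, lapply(split(copies, copies$target_name), function(d) {
    x <- d$copies[!is.na(d$copies)]
    cv <- if (length(x) >= 2 && mean(x) > 0) 100 * stats::sd(x) / mean(x) else NA_real_
    data.frame(target_name = d$target_name[1], target_role = d$target_role[1],
               n = length(x), cv_percent = cv, stringsAsFactors = FALSE)
  }))
  rownames(per_target) <- NULL
  group_mean <- do.call(rbind, lapply(split(per_target, per_target$target_role), function(d) {
    data.frame(target_role = d$target_role[1],
               mean_cv_percent = mean(d$cv_percent, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(group_mean) <- NULL
  list(per_target = per_target, group_mean = group_mean)
}
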