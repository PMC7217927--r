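# Population-level readouts: copy-number distribution, transduction
# efficiency, agreement with the bulk measurement, combination correlations,
# and nonparametric chip-to-chip comparisons.

#' Transduction efficiency from MAP copy calls
#'
#' Percent of cells carrying at least one vector copy: cells with a MAP call
#' of zero are the nontransduced fraction.
#'
#' @param map_copies integer MAP copy calls, one per cell.
#' @return percent of cells with `map_copy >= 1`.
#' @export
transduction_efficiency <- function(map_copies) {
  if (length(map_copies) == 0) {
    vcn_error("no cells to summarise", "vcn_insufficient_data")
  }
  100 * mean(map_copies >= 1)
}

bin_label <- function(lo, hi) {
  if (is.infinite(hi)) sprintf(">=%d", lo)
  else if (lo == hi) sprintf("%d", lo)
  else sprintf("%d-%d", lo, hi)
}

#' Summarise MAP copy calls into a population report
#'
#' Aggregates per-cell integer predictions into the standard release-assay
#' readouts: the proportion of cells at each copy number, a grouped
#' "five-or-more" percentage, cumulative range bins (defaults 0 / 1-4 / 5-10
#' / >=11, reflecting decreasing presumed safety), the mean of the MAP
#' integers, the PCR-based transduction efficiency, and — when a bulk
#' measurement is supplied — the percent difference from it
#' ([delta_vcn()]). The same fields are reported per microfluidic chip.
#'
#' @param cells data.frame with `map_copy` and optionally `chip_id` (per-cell
#'   MAP calls, e.g. `infer_dataset()$cells`).
#' @param pvcn optional bulk population VCN (scalar or the list returned by
#'   [population_vcn()]).
#' @param range_breaks lower edges of the copy ranges above zero.
#' @return list of class `population_summary`.
#' @export
summarize_population <- function(cells, pvcn = NULL, range_breaks = c(1, 5, 11)) {
  if (is.numeric(cells)) cells <- data.frame(map_copy = cells)
  if (nrow(cells) == 0) {
    vcn_error("no cells to summarise", "vcn_insufficient_data")
  }
  stopifnot("map_copy" %in% names(cells))
  calls <- cells$map_copy
  n <- length(calls)

  tab <- table(factor(calls, levels = sort(unique(calls))))
  copy_proportions <- 100 * as.numeric(tab) / n
  names(copy_proportions) <- names(tab)

  lo <- c(0, range_breaks)
  hi <- c(range_breaks - 1, Inf)
  range_bins <- vapply(seq_along(lo), function(i) {
    100 * mean(calls >= lo[i] & calls <= hi[i])
  }, numeric(1))
  names(range_bins) <- mapply(bin_label, lo, hi)

  pv <- if (is.list(pvcn)) pvcn$pvcn_mean else pvcn
  out <- list(
    n_cells = n,
    copy_proportions = copy_proportions,
    grouped_ge5 = 100 * mean(calls >= 5),
    range_bins = range_bins,
    mean_scvcn = mean(calls),
    transduction_efficiency = transduction_efficiency(calls),
    pvcn = pv,
    delta_vcn_percent = if (!is.null(pv)) delta_vcn(pv, mean(calls)) else NA_real_
  )
  if ("chip_id" %in% names(cells) && any(!is.na(cells$chip_id))) {
    out$per_chip <- lapply(split(cells, cells$chip_id), function(d) {
      d$chip_id <- NULL  # avoid recursing into per-chip again
      summarize_population(d, pvcn = pvcn, range_breaks = range_breaks)
    })
  }
  class(out) <- "population_summary"
  out
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population summary over %d cells\n", x$n_cells))
  cat(sprintf("  mean scVCN: %.2f | transduction efficiency: %.1f%%\n",
              x$mean_scvcn, x$transduction_efficiency))
  props <- paste(sprintf("%s: %.1f%%", names(x$copy_proportions),
                         x$copy_proportions), collapse = ", ")
  cat("  copy proportions:", props, "\n")
  bins <- paste(sprintf("%s: %.1f%%", names(x$range_bins), x$range_bins),
                collapse = ", ")
  cat("  range bins:", bins, "\n")
  if (!is.null(x$pvcn) && !is.na(x$delta_vcn_percent)) {
    cat(sprintf("  bulk pVCN %.2f | deltaVCN %.1f%%\n", x$pvcn, x$delta_vcn_percent))
  }
  invisible(x)
}

#' Rank correlations between assay combinations
#'
#' Spearman correlation between each pair of vector/reference assay
#' combinations across cells, using pairwise-complete observations. Pairs
#' with fewer than `min_pairs` complete observations are `NA` and excluded
#' from the mean off-diagonal coefficient.
#'
#' @param measurements long data.frame with `cell_id`, `combination_id`,
#'   `vcn`.
#' @param min_pairs minimum complete observations per pair.
#' @return list with `matrix` (combinations x combinations) and
#'   `mean_offdiag` (mean of the upper-triangle coefficients).
#' @export
combination_correlations <- function(measurements, min_pairs = 3) {
  stopifnot(all(c("cell_id", "combination_id", "vcn") %in% names(measurements)))
  combos <- sort(unique(measurements$combination_id))
  cells <- sort(unique(measurements$cell_id))
  if (length(cells) < 5) {
    vcn_error("combination_correlations needs >= 5 cells", "vcn_insufficient_data")
  }
  wide <- matrix(NA_real_, nrow = length(cells), ncol = length(combos),
                 dimnames = list(cells, combos))
  idx <- cbind(match(measurements$cell_id, cells),
               match(measurements$combination_id, combos))
  wide[idx] <- measurements$vcn

  rho <- suppressWarnings(
    stats::cor(wide, method = "spearman", use = "pairwise.complete.obs")
  )
  # blank out pairs with too few complete observations
  for (i in seq_along(combos)) {
    for (j in seq_along(combos)) {
      if (i == j) next
      if (sum(stats::complete.cases(wide[, c(i, j)])) < min_pairs) {
        rho[i, j] <- NA_real_
      }
    }
  }
  upper <- rho[upper.tri(rho)]
  list(matrix = rho, mean_offdiag = mean(upper, na.rm = TRUE))
}

# Dunn's post hoc test: pairwise z statistics on Kruskal-Wallis mean ranks
# with the standard tie correction; p-values are two-sided normal and
# adjusted for multiplicity.
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  # tie correction term
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  g <- names(mean_ranks)
  pairs <- utils::combn(g, 2)
  res <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    res$z[k] <- z
    res$p_value[k] <- 2 * stats::pnorm(-abs(z))
  }
  res$p_adjusted <- pmin(stats::p.adjust(res$p_value, method = p_adjust), 1)
  res
}

#' Compare copy-number distributions across microfluidic chips
#'
#' Kruskal-Wallis omnibus test over per-chip MAP-call distributions, followed
#' by Dunn's pairwise post hoc z tests with a multiplicity correction
#' (Bonferroni by default). Chips contributing fewer than `min_cells` cells
#' are excluded with a warning.
#'
#' @param cells data.frame with `map_copy` and `chip_id`.
#' @param min_cells minimum cells per chip.
#' @param p_adjust adjustment method name accepted by [stats::p.adjust()].
#' @return list with `kruskal` (the `htest`), `dunn` (pairwise data.frame),
#'   and `excluded_chips`.
#' @export
compare_chips <- function(cells, min_cells = 5, p_adjust = "bonferroni") {
  stopifnot(all(c("map_copy", "chip_id") %in% names(cells)))
  counts <- table(cells$chip_id)
  small <- names(counts)[counts < min_cells]
  if (length(small) > 0) {
    vcn_warn(paste("excluding chips below minimum size:",
                   paste(small, collapse = ", ")), "vcn_small_chip")
    cells <- cells[!cells$chip_id %in% small, , drop = FALSE]
  }
  if (length(unique(cells$chip_id)) < 2) {
    vcn_error("compare_chips needs at least 2 chips of sufficient size",
              "vcn_insufficient_data")
  }
  kw <- stats::kruskal.test(cells$map_copy, factor(cells$chip_id))
  dunn <- dunn_test(cells$map_copy, cells$chip_id, p_adjust = p_adjust)
  list(kruskal = kw, dunn = dunn, excluded_chips = small)
}

#' Two-group distribution comparison
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test between two sets of
#' per-cell copy values. For small samples the exact permutation
#' distribution of U is enumerated (valid in the presence of ties, unlike
#' the classical exact tables); larger samples use the normal approximation
#' with tie correction. The method used is recorded in the result.
#'
#' @param a,b numeric vectors (e.g. MAP calls from two chips), each of at
#'   least `min_cells` values.
#' @param min_cells minimum group size.
#' @param max_exact enumerate the exact permutation distribution when the
#'   number of group assignments `choose(na+nb, na)` is at most this.
#' @return list with `p_value`, `statistic` (U for the first group), and
#'   `method`.
#' @export
compare_two_groups <- function(a, b, min_cells = 5, max_exact = 1e5) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < min_cells || nb < min_cells) {
    vcn_error(sprintf("each group needs >= %d values", min_cells),
              "vcn_insufficient_data")
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  if (choose(na + nb, na) <= max_exact) {
    # exact permutation distribution of U over all group assignments
    idx <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    method <- "Mann-Whitney exact permutation test"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)
    )
    p <- ht$p.value
    method <- "Mann-Whitney normal approximation with tie correction"
  }
  list(p_value = p, statistic = unname(u_obs), method = method)
}
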