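make_cell_table <- function(vcn_by_cell) {
  do.call(rbind, lapply(names(vcn_by_cell), function(id) {
    v <- vcn_by_cell[[id]]
    data.frame(cell_id = id, chip_id = "chip1",
               combination_id = paste0("c", seq_along(v)), vcn = v,
               stringsAsFactors = FALSE)
  }))
}

test_that("cells are filtered at the more-than-3-NAs boundary", {
  tab <- make_cell_table(list(
    four_na = c(1, 1, NA, NA, NA, NA),
    three_na = c(1, 1, 1, NA, NA, NA),
    complete = c(1, 1, 1, 1, 1, 1)
  ))
  cells <- cell_measurements(tab, n_combinations = 6)
  kept <- filter_cells(cells, max_missing = 3)
  expect_setequal(kept$cell_id, c("three_na", "complete"))
  # absent rows count as missing too
  short <- make_cell_table(list(sparse = c(2, 2)))  # only 2 of 6 attempted
  expect_equal(nrow(filter_cells(cell_measurements(short, 6))), 0)
})

test_that("cell summaries report validity counts, mean and SEM", {
  tab <- make_cell_table(list(a = c(1.5, NA, 1.4)))
  cm <- cell_measurements(tab, n_combinations = 6)
  expect_equal(cm$n_valid, 2L)
  expect_equal(cm$n_missing, 4L)
  expect_equal(cm$mean_vcn, 1.45)
  expect_equal(cm$sem_vcn, sd(c(1.5, 1.4)) / sqrt(2))
})

test_that("noise estimation pools within-cell variance on the transformed scale", {
  # hand-computable: within-cell SDs are both 0.1*sqrt(2), pooled identical
  tab <- make_cell_table(list(a = c(1.0, 1.2), b = c(2.0, 2.2)))
  nm <- estimate_noise(tab, transform = "identity", min_cells = 2)
  expect_equal(nm$sigma, sqrt((0.02 + 0.02) / 2), tolerance = 1e-12)
  expect_equal(nm$n_cells, 2L)

  # degenerate no-noise input clips to the floor
  same <- make_cell_table(list(a = rep(2, 6), b = rep(3, 6), c = rep(1, 6),
                               d = rep(2, 6), e = rep(4, 6)))
  nm0 <- estimate_noise(same, transform = "sqrt")
  expect_equal(nm0$sigma, 1e-3)

  # too few cells: fallback with a classed warning
  expect_warning(
    nm_fb <- estimate_noise(tab, transform = "identity", min_cells = 5,
                            default_sigma = 0.25),
    class = "vcn_sigma_fallback"
  )
  expect_equal(nm_fb$sigma, 0.25)
})

test_that("noise estimation recovers a known transformed-scale SD", {
  set.seed(99)
  true_sigma <- 0.15
  tab <- do.call(rbind, lapply(1:100, function(i) {
    k <- sample(1:5, 1)
    y <- k + rnorm(6, 0, true_sigma)  # identity-scale noise
    data.frame(cell_id = sprintf("c%03d", i), chip_id = "chip1",
               combination_id = paste0("m", 1:6), vcn = y,
               stringsAsFactors = FALSE)
  }))
  nm <- estimate_noise(tab, transform = "identity")
  expect_gt(nm$sigma, 0.135)
  expect_lt(nm$sigma, 0.165)
})

test_that("copy likelihood is normal above zero and half-normal at zero", {
  nm <- structure(list(transform = "sqrt", sigma = 0.12,
                       estimation_n = 0L, n_cells = 0L),
                  class = "vcn_noise_model")
  peak <- 1 / (0.12 * sqrt(2 * pi))
  expect_equal(copy_likelihood(sqrt(2), 2, nm), peak, tolerance = 1e-12)
  # half-normal doubling at the fold
  expect_equal(copy_likelihood(0, 0, nm), 2 * peak, tolerance = 1e-12)
  # frozen brute-force densities at y = sqrt(1.4), sigma_eff = 0.12
  y <- sqrt(1.4)
  expect_equal(copy_likelihood(y, 0, nm), 5.143058932e-21, tolerance = 1e-6)
  expect_equal(copy_likelihood(y, 1, nm), 1.036413748, tolerance = 1e-9)
  expect_equal(copy_likelihood(y, 2, nm), 0.5212898336, tolerance = 1e-9)

  expect_error(copy_likelihood(1, -1, nm), class = "vcn_invalid_input")
  expect_error(copy_likelihood(1, 1.5, nm), class = "vcn_invalid_input")
})

test_that("single-cell inference recovers obvious cases and the frozen posterior", {
  nm_small <- structure(list(transform = "sqrt", sigma = 0.05,
                             estimation_n = 0L, n_cells = 0L),
                        class = "vcn_noise_model")
  p3 <- infer_cell(rep(3, 6), nm_small, 0:10)
  expect_equal(p3$map_copy, 3L)
  expect_gt(p3$map_prob, 0.999)

  p0 <- infer_cell(rep(0, 6), nm_small, 0:10)
  expect_equal(p0$map_copy, 0L)

  # frozen fixture: mean VCN 1.4, sigma 0.3, n = 6, uniform prior on 0..10
  nm <- structure(list(transform = "sqrt", sigma = 0.3,
                       estimation_n = 0L, n_cells = 0L),
                  class = "vcn_noise_model")
  pf <- infer_cell(rep(1.4, 6), nm, 0:10)
  expect_equal(pf$map_copy, 1L)
  frozen <- c(2.182128699e-20, 0.6591410497, 0.3407709819, 8.796795479e-05,
              4.437525819e-10, 1.810435431e-16, 1.237713322e-23,
              2.18569592e-31, 1.321733584e-39, 3.329185285e-48,
              4.028099109e-57)
  expect_equal(pf$posterior, frozen, tolerance = 1e-6)
  expect_equal(pf$map_prob, 0.6591410497, tolerance = 1e-8)
})

test_that("posteriors normalise and the MAP matches a brute-force oracle on random cells", {
  set.seed(123)
  nm <- structure(list(transform = "sqrt", sigma = 0.3,
                       estimation_n = 0L, n_cells = 0L),
                  class = "vcn_noise_model")
  support <- 0:15
  for (i in 1:1000) {
    k <- sample(0:12, 1)
    vals <- pmax(k * exp(rnorm(sample(3:6, 1), 0, 0.15)), 0)
    if (k == 0) vals <- rep(0, length(vals))
    p <- infer_cell(vals, nm, support)
    expect_equal(sum(p$posterior), 1, tolerance = 1e-9)
    expect_true(all(p$posterior >= 0 & p$posterior <= 1))
    expect_identical(p$map_copy,
                     as.integer(oracle_map(vals, 0.3, support, "sqrt")))
  }
})

test_that("as sigma shrinks the MAP converges to the nearest transformed integer", {
  support <- 0:10
  set.seed(7)
  for (i in 1:50) {
    m <- runif(1, 0, 9.4)
    # nearest integer in sqrt space (k = 0 scored via the half-normal, which
    # at vanishing sigma is dominated unless y is closest to 0)
    target <- support[which.min(abs(sqrt(m) - sqrt(support)))]
    nm <- structure(list(transform = "sqrt", sigma = 1e-4,
                         estimation_n = 0L, n_cells = 0L),
                    class = "vcn_noise_model")
    p <- infer_cell(rep(m, 6), nm, support)
    expect_identical(p$map_copy, as.integer(target))
  }
})

test_that("MAP is monotone in the cell mean and equals the ML call under a uniform prior", {
  nm <- structure(list(transform = "sqrt", sigma = 0.25,
                       estimation_n = 0L, n_cells = 0L),
                  class = "vcn_noise_model")
  means <- seq(0, 12, by = 0.1)
  maps <- vapply(means, function(m) infer_cell(rep(m, 6), nm, 0:15)$map_copy,
                 integer(1))
  expect_true(all(diff(maps) >= 0))
  for (m in seq(0.2, 11, by = 0.7)) {
    p <- infer_cell(rep(m, 6), nm, 0:15)
    expect_identical(p$map_copy, p$ml_copy)
  }
})

test_that("integer copies are recovered from noisy measurements at the expected rates", {
  run_recovery <- function(seed, cv) {
    sim <- simulate_recovery_data(seed, 200, "empirical_weights",
                                  list(weights = rep(1 / 6, 6)), cv)
    res <- infer_dataset(sim$measurements)
    truth <- sim$truth$cells$true_copies[
      match(res$cells$cell_id, sim$truth$cells$cell_id)]
    mean(res$cells$map_copy == truth)
  }
  expect_gte(run_recovery(201, 0.10), 0.95)
  expect_gte(run_recovery(202, 0.05), 0.99)
})

test_that("the candidate support follows the observed range with a floor", {
  expect_equal(copy_support(c(1.1, 2.3)), 0:5)          # K_min binds
  expect_equal(copy_support(42.6), 0:45)                # ceiling + margin
  expect_equal(copy_support(numeric(0)), 0:5)
})

test_that("dataset inference is deterministic and validates its input", {
  sim <- simulate_recovery_data(55, 40, "zero_truncated_poisson",
                                list(mean_copies = 2), 0.1)
  r1 <- infer_dataset(sim$measurements)
  r2 <- infer_dataset(sim$measurements)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$posteriors[[10]]$posterior, r2$posteriors[[10]]$posterior)

  empty <- sim$measurements
  empty$vcn <- NA_real_
  expect_error(infer_dataset(empty), class = "vcn_insufficient_data")
})
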