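test_that("a single-cell fit reproduces the closed-form Poisson MLE", {
  g <- make_grid(1, 1, 25, seed = 1)
  cv <- make_covariates(g, 1, seed = 1)
  A <- saltwater_area(g)
  C <- 7; a <- 0.05
  survey <- list(
    tracks_us = data.frame(cell_id = integer(0), day = integer(0),
                           photos = integer(0),
                           photos_with_tracks = integer(0)),
    tracks_ru = data.frame(cell_id = integer(0), day = integer(0),
                           length_km = numeric(0), tracks = integer(0)),
    counts_us_thermal = data.frame(cell_id = 1, day = 1, count = C,
                                   footprint_km2 = a * A),
    counts_us_aux = data.frame(cell_id = integer(0), day = integer(0),
                               count = integer(0),
                               footprint_km2 = numeric(0)),
    counts_ru = data.frame(cell_id = integer(0), day = integer(0),
                           count = integer(0), length_km = numeric(0)),
    distances = data.frame(cell_id = integer(0), day = integer(0),
                           distance_m = numeric(0)),
    trials = data.frame(detected = 8, trials = 12),
    groups = data.frame(group_id = 1:4, platform = "us",
                        size = c(1, 2, 1, 1)))
  fit <- fit_abundance(survey, g, cv, g0 = 1,
                       smooths = build_smooths(cv, covariates = character(0)))
  # with one cell pi = 1; profile MLEs: p_us = D/n, N = C / (p_us a)
  expect_equal(fit$p_us[["Estimate"]], 8 / 12, tolerance = 1e-4)
  expect_equal(fit$N[["Estimate"]], C / ((8 / 12) * a), tolerance = 1e-3)
  expect_equal(fit$mu_g[["Estimate"]], mean(c(1, 2, 1, 1)), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("the Laplace approximation matches adaptive quadrature on a toy model", {
  y <- c(18, 22, 25); mu <- 3; tau <- 0.5
  lap <- laplace_toy_nll(y, mu, tau)
  joint <- function(u) {
    vapply(u, function(ui) {
      exp(sum(dpois(y, exp(mu + ui), log = TRUE)) +
            dnorm(ui, 0, tau, log = TRUE))
    }, numeric(1))
  }
  quad <- -log(integrate(joint, -8 * tau, 8 * tau, rel.tol = 1e-12)$value)
  expect_equal(lap, quad, tolerance = 1e-3)
})

test_that("fitting the model to its own expected counts recovers abundance", {
  N_true <- 600
  g <- make_grid(10, 10, 25, seed = 41)
  cv <- make_covariates(g, 3, seed = 41)
  sc <- sim_scenario(S = 100, T_days = 3, true_N = N_true, seed = 41)
  Pi <- polarabund:::true_occupancy(g, cv, sc)
  A <- saltwater_area(g)
  all_cells <- expand.grid(cell_id = g$cell_id, day = 1:3)
  # full coverage (a = 1), certain detection, counts at the expected value
  survey <- list(
    tracks_us = data.frame(cell_id = integer(0), day = integer(0),
                           photos = integer(0),
                           photos_with_tracks = integer(0)),
    tracks_ru = data.frame(cell_id = integer(0), day = integer(0),
                           length_km = numeric(0), tracks = integer(0)),
    counts_us_thermal = data.frame(
      cell_id = all_cells$cell_id, day = all_cells$day,
      count = round(N_true * Pi[cbind(all_cells$cell_id, all_cells$day)]),
      footprint_km2 = A[all_cells$cell_id]),
    counts_us_aux = data.frame(cell_id = integer(0), day = integer(0),
                               count = integer(0),
                               footprint_km2 = numeric(0)),
    counts_ru = data.frame(cell_id = integer(0), day = integer(0),
                           count = integer(0), length_km = numeric(0)),
    distances = data.frame(cell_id = integer(0), day = integer(0),
                           distance_m = numeric(0)),
    trials = data.frame(detected = 12, trials = 12),
    groups = data.frame(group_id = 1:5, platform = "us",
                        size = c(1, 2, 1, 2, 1)))
  fit <- suppressMessages(fit_abundance(
    survey, g, cv, g0 = 1,
    init = list(logit_p_us = qlogis(1 - 1e-9)),
    map = list(logit_p_us = factor(NA))))
  expect_lt(abs(fit$N[["Estimate"]] - N_true) / N_true, 0.05)
})

test_that("fitted occupancy surfaces are distributions gated by open water", {
  sf <- small_fit()
  fit <- sf$fit; sim <- sf$sim
  expect_true(fit$converged)
  # every day's occupancy probabilities sum to one
  expect_true(all(abs(colSums(fit$pi_hat) - 1) < 1e-12))
  # cells flagged as open water carry essentially no probability
  w99 <- matrix(sim$cov$water99, nrow = nrow(sim$grid))
  if (any(w99 == 1) && any(w99 == 0)) {
    expect_lt(max(fit$pi_hat[w99 == 1]), 1e-15)
  }
  # abundance must be positive with a finite interval
  expect_true(all(is.finite(fit$N_star)))
  expect_true(fit$N_star[["lower"]] <= fit$N_star[["estimate"]])
  expect_true(fit$N_star[["estimate"]] <= fit$N_star[["upper"]])
})

test_that("log-based intervals are multiplicatively symmetric", {
  sf <- small_fit()
  fit <- sf$fit
  ns <- fit$N_star
  expect_equal(ns[["lower"]] * ns[["upper"]], ns[["estimate"]]^2,
               tolerance = 1e-6)
  rt <- fit$region_table
  ok <- is.finite(rt$lower) & rt$estimate > 0
  expect_equal(rt$lower[ok] * rt$upper[ok], rt$estimate[ok]^2,
               tolerance = 1e-6)
  # total_abundance exposes the same interval
  ta <- total_abundance(fit)
  expect_equal(ta$estimate, ns[["estimate"]])
  expect_equal(ta$lower * ta$upper, ta$estimate^2, tolerance = 1e-6)
})

test_that("empty surveys are rejected with a clear message", {
  sim <- small_sim(seed = 17)
  sv <- sim$survey
  sv$counts_us_thermal$count <- 0L
  sv$counts_us_aux$count <- 0L
  sv$counts_ru$count <- 0L
  sv$distances <- sv$distances[0, ]
  expect_error(suppressMessages(fit_abundance(sv, sim$grid, sim$cov, g0 = 1)),
               "no bear groups")
  expect_error(build_model_frame(sim$survey, sim$grid, sim$cov),
               "g0")
})
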