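test_that("coverage fractions follow the platform-specific formulas", {
  expect_equal(coverage_fraction("ru", 500, length_km = 10), 0.024)
  expect_equal(coverage_fraction("us", 625, footprint_km2 = 6.25), 0.01)
  expect_equal(coverage_fraction("ru", 500, length_km = 600), 1)
  expect_equal(coverage_fraction("us", 100, footprint_km2 = 0), 0)
  expect_error(coverage_fraction("ru", 0, length_km = 5), "without saltwater")
})

test_that("the count likelihood is a normalized thinned-Poisson pmf", {
  # zero counts: nll equals the summed means
  pi_v <- c(0.2, 0.05); p_v <- c(0.01, 0.03); N <- 500
  expect_equal(count_nll(c(0, 0), N, pi_v, p_v), sum(N * pi_v * p_v))
  # xi = 1 reduces auxiliary rows to the primary form
  expect_equal(count_nll(c(2, 1), N, pi_v, p_v, xi = 1),
               count_nll(c(2, 1), N, pi_v, p_v))
  # enumeration oracle: pmf sums to 1 over the outcome space
  mu <- 500 * 0.2 * 0.01
  total <- sum(vapply(0:50, function(y) exp(-count_nll(y, 500, 0.2, 0.01)),
                      numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(count_nll(c(-1, 0), N, pi_v, p_v), "nonnegative")
  expect_error(count_nll(c(1, 0), N, pi_v, c(0, 0.1)), "zero detection")
})

test_that("shifted-Poisson group size MLE is the sample mean", {
  expect_equal(groupsize_mle(c(1, 1, 1)), 1)
  expect_equal(groupsize_mle(c(1, 1, 2)), 4 / 3)
  # optimality of the MLE on random samples
  set.seed(8)
  for (r in 1:20) {
    gsz <- 1 + rpois(40, runif(1, 0.05, 2))
    m <- groupsize_mle(gsz)
    if (m == 1) next
    expect_lte(groupsize_nll(gsz, m), groupsize_nll(gsz, m + 0.01))
    expect_lte(groupsize_nll(gsz, m), groupsize_nll(gsz, max(1, m - 0.01)))
  }
  expect_error(groupsize_nll(c(0, 2), 1.5), ">= 1")
  expect_error(groupsize_mle(numeric(0)), "no group sizes")
})

test_that("the joint likelihood is the sum of its submodels", {
  sim <- small_sim(seed = 17)
  frame <- suppressMessages(
    build_model_frame(sim$survey, sim$grid, sim$cov, g0 = 0.8))
  np <- natural_params(frame)
  total <- joint_nll(np, frame)
  parts <- attr(total, "parts")
  expect_equal(as.numeric(total), sum(parts), tolerance = 1e-12)

  # recompute each part independently of joint_nll
  surf <- polarabund:::predictor_surfaces(np, frame)
  Piv <- as.vector(surf$pi)
  p_rus <- halfnormal_p(np$sigma, frame$w, frame$g0)
  track <- track_nll(list(us = sim$survey$tracks_us,
                          ru = sim$survey$tracks_ru),
                     list(beta = np$beta, eta = np$eta), sim$cov)
  counts <- count_nll(frame$th_y, np$N, Piv[frame$th_idx],
                      np$p_us * frame$th_a) +
    count_nll(frame$ax_y, np$N, Piv[frame$ax_idx], np$p_us * frame$ax_a,
              xi = np$xi) +
    count_nll(frame$cru_y, np$N, Piv[frame$cru_idx], p_rus * frame$cru_a)
  det <- flyover_nll(frame$fly_D, frame$fly_n, np$p_us) +
    distance_nll(frame$distances, np$sigma, frame$w)
  gs <- groupsize_nll(frame$gsize, np$mu_g)
  pri <- alpha_prior_nll(np$alpha, np$lambda, frame$smooths)
  expect_equal(as.numeric(total), track + counts + det + gs + pri,
               tolerance = 1e-10)
})

test_that("the compiled joint objective equals the reference implementation", {
  for (s in c(17, 23)) {
    sim <- small_sim(seed = s)
    frame <- suppressMessages(
      build_model_frame(sim$survey, sim$grid, sim$cov, g0 = 0.6))
    np <- natural_params(frame, seed = s)
    obj <- TMB::MakeADFun(data = polarabund:::tmb_data(frame),
                          parameters = transformed_params(np),
                          random = NULL, DLL = "polarabund", silent = TRUE)
    expect_equal(as.numeric(obj$fn(obj$par)),
                 as.numeric(joint_nll(np, frame)), tolerance = 1e-8)
  }
})

test_that("the joint likelihood is finite at generating parameters", {
  for (s in 101:110) {
    sim <- small_sim(seed = s)
    frame <- suppressMessages(
      build_model_frame(sim$survey, sim$grid, sim$cov,
                        g0 = sim$scenario$g0))
    sc <- sim$scenario
    np <- list(N = sc$true_N, alpha = rep(0, ncol(frame$smooths$X)),
               alpha_tracks = sc$true_alpha_tracks,
               lambda = rep(10, length(frame$smooths$S)),
               beta = sc$true_beta, eta = sc$true_eta, xi = sc$true_xi,
               sigma = sc$true_sigma, p_us = sc$true_p_us,
               mu_g = sc$true_mu_g)
    expect_true(is.finite(joint_nll(np, frame)))
  }
})

test_that("with no observations the joint likelihood reduces to the priors", {
  sim <- small_sim(seed = 17)
  empty <- list(
    tracks_us = data.frame(cell_id = integer(0), day = integer(0),
                           photos = integer(0),
                           photos_with_tracks = integer(0)),
    tracks_ru = data.frame(cell_id = integer(0), day = integer(0),
                           length_km = numeric(0), tracks = integer(0)),
    counts_us_thermal = data.frame(cell_id = integer(0), day = integer(0),
                                   count = integer(0),
                                   footprint_km2 = numeric(0)),
    counts_us_aux = data.frame(cell_id = integer(0), day = integer(0),
                               count = integer(0),
                               footprint_km2 = numeric(0)),
    counts_ru = data.frame(cell_id = integer(0), day = integer(0),
                           count = integer(0), length_km = numeric(0)),
    distances = data.frame(cell_id = integer(0), day = integer(0),
                           distance_m = numeric(0)),
    trials = data.frame(detected = 0, trials = 0),
    groups = data.frame(group_id = integer(0), platform = character(0),
                        size = integer(0)))
  frame <- suppressMessages(
    build_model_frame(empty, sim$grid, sim$cov, g0 = 1))
  np <- natural_params(frame)
  expect_equal(as.numeric(joint_nll(np, frame)),
               alpha_prior_nll(np$alpha, np$lambda, frame$smooths),
               tolerance = 1e-10)
})
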