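# shared fixtures, all generated in code

# small survey (10 x 10 grid, 5 days) for fast unit tests
small_sim <- function(seed = 11, N = 300, T_days = 5) {
  sc <- sim_scenario(S = 100, T_days = T_days, true_N = N, seed = seed)
  g <- make_grid(10, 10, 25, seed = seed)
  cv <- make_covariates(g, T_days, seed = seed)
  sv <- simulate_survey(g, cv, sc)
  list(scenario = sc, grid = g, cov = cv, survey = sv)
}

# default-condition survey (20 x 20 grid, 10 days, N = 600 groups)
default_sim <- function(seed = 1) {
  sc <- sim_scenario(seed = seed)
  g <- make_grid(20, 20, 25, seed = seed)
  cv <- make_covariates(g, sc$T_days, seed = seed)
  sv <- simulate_survey(g, cv, sc)
  list(scenario = sc, grid = g, cov = cv, survey = sv)
}

# one small fitted model, built lazily and reused across test files
.fit_cache <- new.env(parent = emptyenv())
small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    sim <- small_sim()
    .fit_cache$sim <- sim
    .fit_cache$fit <- suppressMessages(
      fit_abundance(sim$survey, sim$grid, sim$cov, g0 = 1))
  }
  list(fit = .fit_cache$fit, sim = .fit_cache$sim)
}

# natural-scale parameter list at a frame's starting values, with optional
# perturbed spline coefficients
natural_params <- function(frame, alpha = NULL, seed = 5) {
  pars <- polarabund:::init_params(frame)
  if (is.null(alpha)) {
    set.seed(seed)
    alpha <- rnorm(length(pars$alpha), 0, 0.3)
  }
  list(N = exp(pars$log_N), alpha = alpha, alpha_tracks = 0.1,
       lambda = exp(pars$log_lambda), beta = pars$beta,
       eta = exp(pars$log_eta), xi = exp(pars$log_xi),
       sigma = exp(pars$log_sigma), p_us = plogis(pars$logit_p_us),
       mu_g = 1 + exp(pars$log_mu_g_m1))
}

# transformed-scale list matching a natural-scale list (TMB layout)
transformed_params <- function(np) {
  list(log_N = log(np$N), alpha = np$alpha, alpha_tracks = np$alpha_tracks,
       log_lambda = log(np$lambda), beta = np$beta,
       log_eta = log(np$eta), log_xi = log(np$xi),
       log_sigma = log(np$sigma), logit_p_us = qlogis(np$p_us),
       log_mu_g_m1 = log(np$mu_g - 1))
}
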