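test_that("the track design matrix is the documented polynomial expansion", {
  g <- make_grid(10, 10, 25, seed = 5)
  cv <- make_covariates(g, 4, seed = 5)
  X <- build_track_design(cv)
  expect_equal(dim(X), c(400, 6))
  expect_equal(colnames(X), c("intercept", "d", "d2", "ice", "ice2", "rsf"))
  # polynomial expansion of a single row
  cv2 <- cv[1, , drop = FALSE]
  cv2$dist_land_std <- 2; cv2$ice <- 0.5; cv2$rsf <- 0.3
  attr(cv2, "S") <- 1; attr(cv2, "T_days") <- 1
  expect_equal(unname(build_track_design(cv2)[1, ]),
               c(1, 2, 4, 0.5, 0.25, 0.3))
  cv2$dist_land_std <- 0; cv2$ice <- 0; cv2$rsf <- 0
  expect_equal(unname(build_track_design(cv2)[1, ]), c(1, 0, 0, 0, 0, 0))
  expect_error(build_track_design(cv, cell = 9999, day = 1),
               "no covariates")
  cv3 <- cv; cv3$ice[5] <- NA
  expect_error(build_track_design(cv3), "missing covariate")
})

test_that("track intensity and photo-presence probability behave as closed forms", {
  expect_equal(track_intensity(c(1, 0, 0, 0, 0, 0), rep(0, 6)), 1)
  x <- c(1, 1, 1, 1, 1, 1)
  b <- rep(log(2) / 6, 6)
  expect_equal(track_intensity(x, b), 2)
  expect_equal(track_intensity(x, rep(-200, 6)), 0)

  expect_equal(photo_track_prob(0), 0)
  expect_equal(photo_track_prob(1e9), 1)
  expect_equal(photo_track_prob(100, 0.012), 1 - exp(-1.2))
  expect_equal(photo_track_prob(100, 0.012), 0.69881, tolerance = 1e-5)
  # doubling intensity while halving the footprint leaves phi unchanged
  Z <- c(0.5, 3, 40)
  expect_equal(photo_track_prob(Z, 0.012), photo_track_prob(2 * Z, 0.006))
  # monotone in both arguments
  expect_true(all(diff(photo_track_prob(c(1, 5, 20, 100))) > 0))
  expect_lt(photo_track_prob(10, 0.01), photo_track_prob(10, 0.02))
  expect_error(photo_track_prob(-1), "nonnegative")
})

test_that("the track likelihood matches hand-computed pmfs and normalizes", {
  g <- make_grid(2, 2, 25, seed = 1)
  cv <- make_covariates(g, 1, seed = 1)
  # choose beta so that phi = 0.5 for cell 1: Z = -log(0.5)/B
  Zt <- -log(0.5) / 0.012
  X1 <- build_track_design(cv)[1, ]
  beta <- c(log(Zt) / X1[1], 0, 0, 0, 0, 0)  # intercept-only
  params <- list(beta = beta, eta = 1)
  d_us <- list(us = data.frame(cell_id = 1, day = 1, photos = 2,
                               photos_with_tracks = 1), ru = NULL)
  expect_equal(track_nll(d_us, params, cv), -log(2 * 0.5 * 0.5))

  # Poisson at zero: contribution equals the mean
  L <- 3.7; eta <- 0.21
  lam <- L * eta * track_intensity(X1, beta)
  d_ru <- list(us = NULL, ru = data.frame(cell_id = 1, day = 1,
                                          length_km = L, tracks = 0))
  expect_equal(track_nll(d_ru, list(beta = beta, eta = eta), cv), lam)

  # brute-force normalization over outcomes
  p_sum <- sum(vapply(0:2, function(y) {
    d <- list(us = data.frame(cell_id = 1, day = 1, photos = 2,
                              photos_with_tracks = y))
    exp(-track_nll(d, params, cv))
  }, numeric(1)))
  expect_equal(p_sum, 1, tolerance = 1e-12)
  p_sum_ru <- sum(vapply(0:150, function(y) {
    d <- list(ru = data.frame(cell_id = 1, day = 1, length_km = L, tracks = y))
    exp(-track_nll(d, list(beta = beta, eta = eta), cv))
  }, numeric(1)))
  expect_equal(p_sum_ru, 1, tolerance = 1e-10)

  expect_error(track_nll(list(us = data.frame(cell_id = 1, day = 1,
                                              photos = 2,
                                              photos_with_tracks = 3)),
                         params, cv), "photos")
})

# maximize the track submodel alone over (beta, log eta)
track_mle <- function(sv, cv, start) {
  d <- list(us = sv$tracks_us, ru = sv$tracks_ru)
  fn <- function(par) {
    track_nll(d, list(beta = par[1:6], eta = exp(par[7])), cv)
  }
  opt <- optim(start, fn, method = "BFGS", control = list(maxit = 500))
  H <- optimHess(opt$par, fn)
  list(par = opt$par, se = sqrt(diag(solve(H))))
}

test_that("track parameters are recovered from simulated photo and observer data", {
  hits <- 0; n_rep <- 25
  truth <- sim_scenario()
  start <- c(truth$true_beta, log(truth$true_eta))
  for (r in seq_len(n_rep)) {
    sim <- small_sim(seed = 300 + r)
    m <- tryCatch(track_mle(sim$survey, sim$cov, start), error = function(e) NULL)
    if (is.null(m)) next
    tru <- c(sim$scenario$true_beta, log(sim$scenario$true_eta))
    if (all(abs(m$par - tru) <= 3 * m$se)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("the observer scaling is only identified jointly with photo data", {
  sim <- small_sim(seed = 33)
  sv <- sim$survey; cv <- sim$cov
  b <- sim$scenario$true_beta; eta <- sim$scenario$true_eta
  base_ru <- track_nll(list(ru = sv$tracks_ru),
                       list(beta = b, eta = eta), cv)
  base_all <- track_nll(list(us = sv$tracks_us, ru = sv$tracks_ru),
                        list(beta = b, eta = eta), cv)
  for (delta in c(-0.5, 0.3, 1)) {
    b2 <- b; b2[1] <- b[1] + delta
    eta2 <- eta * exp(-delta)
    # without photo rows the likelihood is flat along intercept + log eta
    expect_equal(track_nll(list(ru = sv$tracks_ru),
                           list(beta = b2, eta = eta2), cv),
                 base_ru, tolerance = 1e-8)
    # with photo rows it is not
    expect_gt(abs(track_nll(list(us = sv$tracks_us, ru = sv$tracks_ru),
                            list(beta = b2, eta = eta2), cv) - base_all),
              1)
  }
})
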