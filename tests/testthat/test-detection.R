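test_that("flyover trials give the exact binomial estimate", {
  est <- flyover_estimate(8, 12)
  expect_equal(round(est$p_hat, 2), 0.67)
  expect_equal(round(est$se, 2), 0.14)
  expect_equal(flyover_estimate(0, 12), list(p_hat = 0, se = 0))
  expect_equal(flyover_estimate(12, 12), list(p_hat = 1, se = 0))
  expect_error(flyover_estimate(1, 0), "at least one")
  expect_error(flyover_estimate(13, 12), "lie in")
  # the estimate is the binomial MLE: nudging p in either direction can
  # only lower the log likelihood
  for (D in c(3, 8, 11)) {
    p_hat <- flyover_estimate(D, 12)$p_hat
    ll <- function(p) dbinom(D, 12, p, log = TRUE)
    expect_gte(ll(p_hat), ll(p_hat - 0.01))
    expect_gte(ll(p_hat), ll(min(p_hat + 0.01, 1)))
  }
})

test_that("half-normal average detection matches the closed form and quadrature", {
  # saturation limits
  expect_equal(halfnormal_p(1e9, 600, 1), 1, tolerance = 1e-9)
  expect_equal(halfnormal_p(300, 1e-3, 1), 1, tolerance = 1e-9)
  # closed form sigma sqrt(pi/2) erf(w / (sigma sqrt 2)) / w
  s <- 300; w <- 600
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  closed <- s * sqrt(pi / 2) * erf(w / (s * sqrt(2))) / w
  expect_equal(halfnormal_p(s, w, 1), closed, tolerance = 1e-12)
  expect_equal(round(halfnormal_p(s, w, 1), 3), 0.598)
  # independent quadrature oracle
  quad <- integrate(function(x) exp(-x^2 / (2 * s^2)), 0, w,
                    rel.tol = 1e-10)$value / w
  expect_equal(halfnormal_p(s, w, 1), quad, tolerance = 1e-8)
  # strictly increasing in sigma and g0, bounded by g0
  sig <- c(50, 150, 300, 600, 2000)
  expect_true(all(diff(halfnormal_p(sig, w, 1)) > 0))
  expect_equal(halfnormal_p(s, w, 0.6) / halfnormal_p(s, w, 1), 0.6)
  expect_true(all(halfnormal_p(sig, w, 0.8) <= 0.8))
  expect_error(halfnormal_p(-1, 600, 1), "positive")
})

test_that("the uniform-half-normal mixture is continuous and reduces correctly", {
  s <- 150; w <- 600; bp <- 350
  # quadrature of the piecewise detection function
  gfun <- function(x) ifelse(x <= bp, 1, exp(-(x - bp)^2 / (2 * s^2)))
  quad <- integrate(gfun, 0, w, rel.tol = 1e-10)$value / w
  expect_equal(mixture_p(s, w, bp, 1), quad, tolerance = 1e-8)
  # infinite scale: detection certain everywhere
  expect_equal(mixture_p(1e9, w, bp, 0.8), 0.8, tolerance = 1e-9)
  # vanishing breakpoint: plain half-normal
  expect_equal(mixture_p(s, w, 1e-12, 1), halfnormal_p(s, w, 1),
               tolerance = 1e-9)
  expect_error(mixture_p(s, w, w, 1), "breakpoint")
})

test_that("distance fitting maximizes the truncated detection likelihood", {
  # grid-search oracle for a degenerate sample
  d0 <- rep(200, 5)
  f <- fit_distance(d0, w = 600)
  grid_ls <- seq(log(50), log(5000), length.out = 4001)
  nd <- function(ls) {
    s <- exp(ls)
    -sum(log(exp(-d0^2 / (2 * s^2)))) +
      length(d0) * log(s * sqrt(2 * pi) * (pnorm(600 / s) - 0.5))
  }
  oracle <- exp(grid_ls[which.min(vapply(grid_ls, nd, numeric(1)))])
  expect_equal(f$sigma, oracle, tolerance = 1e-3)
  expect_true(f$convergence$converged)

  # Monte-Carlo recovery from a truncated half-normal sample
  set.seed(11)
  u <- runif(200)
  sig <- 200; w <- 600
  x <- sig * qnorm(0.5 + u * (pnorm(w / sig) - 0.5))
  fhat <- fit_distance(x, w = w)
  expect_lt(abs(fhat$sigma - sig) / sig, 0.15)

  # the fitted truncated density integrates to one
  dens <- function(z) {
    exp(-z^2 / (2 * fhat$sigma^2)) /
      (fhat$sigma * sqrt(2 * pi) * (pnorm(w / fhat$sigma) - 0.5))
  }
  expect_equal(integrate(dens, 0, w, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)

  # with one estimated parameter each, the AIC gap is twice the nll gap
  fm <- fit_distance(x, w = w, form = "mixture")
  expect_equal(fm$AIC - fhat$AIC, 2 * (fm$nll - fhat$nll))
  expect_error(fit_distance(numeric(0)), "at least two")
  expect_error(fit_distance(c(10, 700), w = 600), "lie in")
})
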