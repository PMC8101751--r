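#' Randomized quantile residuals for discrete submodels
#'
#' For an observed count `y` under a fitted discrete distribution, the
#' randomized quantile residual is `R = P(Y < y) + u * P(Y = y)` with `u` a
#' Uniform(0,1) deviate — the lower-CDF convention, under which residuals
#' from a correctly specified model are exactly Uniform(0,1). The
#' randomization smooths over the probability mass at the observed value,
#' which makes lack of fit visible for counts that otherwise clump at a few
#' small values.
#'
#' @param y observed counts.
#' @param dist `"poisson"` or `"binomial"`.
#' @param mu Poisson means (for `dist = "poisson"`).
#' @param size,prob binomial index and success probability
#'   (for `dist = "binomial"`).
#' @param u uniform deviates, one per observation (drawn if omitted; supply
#'   them for reproducible diagnostics).
#' @return residuals in `[0, 1]`.
#' @export
rqr <- function(y, dist = c("poisson", "binomial"), mu = NULL,
                size = NULL, prob = NULL, u = NULL) {
  dist <- match.arg(dist)
  if (is.null(u)) u <- stats::runif(length(y))
  if (any(u < 0 | u > 1)) stop("uniform deviates must lie in [0, 1]")
  if (dist == "poisson") {
    if (is.null(mu) || any(mu < 0)) stop("valid Poisson means are required")
    stats::ppois(y - 1, mu) + u * stats::dpois(y, mu)
  } else {
    if (is.null(size) || is.null(prob) || any(prob < 0 | prob > 1))
      stop("valid binomial size and probability are required")
    stats::pbinom(y - 1, size, prob) + u * stats::dbinom(y, size, prob)
  }
}

#' Chi-squared uniformity test on randomized quantile residuals
#'
#' Bins residuals into `bins` equal-width cells on `[0, 1]` and compares
#' observed to expected counts with a chi-squared statistic on `bins - 1`
#' degrees of freedom.
#'
#' @param residuals values in `[0, 1]`.
#' @param bins number of equal bins (default 10).
#' @return list with `statistic`, `df`, `p_value`, `bin_counts`.
#' @export
uniformity_chisq <- function(residuals, bins = 10) {
  if (!length(residuals)) stop("no residuals supplied")
  if (any(residuals < 0 | residuals > 1))
    stop("residuals must lie in [0, 1]")
  if (length(residuals) < bins)
    warning("fewer residuals than bins; the chi-squared test is unreliable")
  cuts <- cut(residuals, breaks = seq(0, 1, length.out = bins + 1),
              include.lowest = TRUE)
  obs <- as.numeric(table(cuts))
  expd <- length(residuals) / bins
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, df = bins - 1,
       p_value = stats::pchisq(stat, df = bins - 1, lower.tail = FALSE),
       bin_counts = obs)
}

#' Goodness-of-fit report for the four encounter submodels
#'
#' Computes randomized quantile residuals for each data stream of a fitted
#' joint model — photo track presence (binomial), observer track counts
#' (Poisson), thermal+auxiliary counts (Poisson) and distance-platform
#' counts (Poisson) — and the 10-bin chi-squared uniformity test for each.
#'
#' @param fit an `abund_fit`.
#' @param seed seed for the uniform randomization (recorded in the output
#'   so diagnostic runs are reproducible).
#' @param bins bins for the uniformity test.
#' @return list of class `"rqr_report"`: per-submodel residual vectors and
#'   a summary table of chi-squared statistics and p-values.
#' @export
rqr_diagnostics <- function(fit, seed = 1L, bins = 10) {
  frame <- fit$frame
  rng <- local_rng(seed)
  Z <- as.vector(fit$Z_hat)
  Pi <- as.vector(fit$pi_hat)
  N <- fit$N[["Estimate"]]
  p_us <- fit$p_us[["Estimate"]]
  p_rus <- fit$p_rus[["Estimate"]]
  eta <- fit$eta[["Estimate"]]
  xi <- fit$xi[["Estimate"]]

  sets <- list(
    tracks_us = rqr(frame$us_T, "binomial", size = frame$us_P,
                    prob = photo_track_prob(Z[frame$us_idx], frame$B),
                    u = rng$runif(length(frame$us_T))),
    tracks_ru = rqr(frame$ru_T, "poisson",
                    mu = frame$ru_L * eta * Z[frame$ru_idx],
                    u = rng$runif(length(frame$ru_T))),
    counts_us = rqr(c(frame$th_y, frame$ax_y), "poisson",
                    mu = c(N * Pi[frame$th_idx] * p_us * frame$th_a,
                           xi * N * Pi[frame$ax_idx] * p_us * frame$ax_a),
                    u = rng$runif(length(frame$th_y) + length(frame$ax_y))),
    counts_ru = rqr(frame$cru_y, "poisson",
                    mu = N * Pi[frame$cru_idx] * p_rus * frame$cru_a,
                    u = rng$runif(length(frame$cru_y))))
  tests <- lapply(sets, uniformity_chisq, bins = bins)
  summary <- data.frame(
    submodel = names(sets),
    n = vapply(sets, length, integer(1)),
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    row.names = NULL)
  structure(list(residuals = sets, tests = tests, summary = summary,
                 seed = seed, bins = bins),
            class = "rqr_report")
}

#' @export
print.rqr_report <- function(x, ...) {
  cat("Randomized quantile residual diagnostics (", x$bins,
      "-bin chi-squared)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
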