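#' Thermal detection probability from experimental flyovers
#'
#' Binomial point estimate and standard error of the probability that the
#' thermal detection pipeline finds a bear group present in the imagery,
#' from repeated experimental flyovers of known groups.
#'
#' @param detected number of groups detected (`D`).
#' @param trials number of first flyovers (`n`).
#' @return list with `p_hat = D/n` and `se = sqrt(p_hat (1 - p_hat) / n)`.
#' @examples
#' flyover_estimate(8, 12)   # p_hat 0.67, se 0.14
#' @export
flyover_estimate <- function(detected, trials) {
  if (trials < 1) stop("at least one flyover trial is required")
  if (detected < 0 || detected > trials)
    stop("'detected' must lie in [0, trials]")
  p <- detected / trials
  list(p_hat = p, se = sqrt(p * (1 - p) / trials))
}

#' Average half-normal detection probability within the truncation distance
#'
#' The per-group detection probability for the visual/photographic platform:
#' the average of a half-normal detection function over perpendicular
#' distances `[0, w]`, scaled by the trackline detection probability `g(0)`,
#' \deqn{p = g(0) \frac{1}{w}\int_0^w \exp(-x^2 / 2\sigma^2)\,dx
#'         = g(0)\,\sigma\sqrt{\pi/2}\,\mathrm{erf}(w/(\sigma\sqrt2))/w.}
#'
#' @param sigma half-normal scale (same units as `w`), positive.
#' @param w truncation distance (default 600 m).
#' @param g0 probability of detection on the trackline, fixed by scenario
#'   (never estimated here).
#' @return probability in `(0, g0]`.
#' @export
halfnormal_p <- function(sigma, w = 600, g0 = 1) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (any(w <= 0)) stop("'w' must be positive")
  if (any(g0 <= 0 | g0 > 1)) stop("'g0' must lie in (0, 1]")
  g0 * sigma * sqrt(2 * pi) * (stats::pnorm(w / sigma) - 0.5) / w
}

#' Average detection probability for the uniform-half-normal mixture
#'
#' Detection is certain (up to `g(0)`) out to a photo-reach breakpoint, then
#' declines half-normally to the truncation distance; the decline is
#' continuous at the breakpoint. This form reflects platforms where
#' photographs fully cover distances up to a fixed reach and human observers
#' take over beyond it.
#'
#' @param sigma half-normal scale of the declining segment.
#' @param w truncation distance (default 600 m).
#' @param breakpoint photo-reach distance (default 350 m); must be < `w`.
#' @param g0 trackline detection probability.
#' @return probability in `(0, g0]`.
#' @export
mixture_p <- function(sigma, w = 600, breakpoint = 350, g0 = 1) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (breakpoint < 0 || breakpoint >= w)
    stop("'breakpoint' must lie in [0, w)")
  if (any(g0 <= 0 | g0 > 1)) stop("'g0' must lie in (0, 1]")
  tail_int <- sigma * sqrt(2 * pi) * (stats::pnorm((w - breakpoint) / sigma) - 0.5)
  g0 * (breakpoint + tail_int) / w
}

# unnormalized detection function values for the two forms
detfun_value <- function(x, sigma, form, breakpoint) {
  switch(form,
    halfnormal = exp(-x^2 / (2 * sigma^2)),
    mixture = ifelse(x <= breakpoint, 1,
                     exp(-(x - breakpoint)^2 / (2 * sigma^2))),
    stop("unknown detection function form: ", form))
}

# integral of the unnormalized detection function over [0, w]
detfun_integral <- function(sigma, w, form, breakpoint) {
  switch(form,
    halfnormal = sigma * sqrt(2 * pi) * (stats::pnorm(w / sigma) - 0.5),
    mixture = breakpoint +
      sigma * sqrt(2 * pi) * (stats::pnorm((w - breakpoint) / sigma) - 0.5),
    stop("unknown detection function form: ", form))
}

#' Fit a detection function to perpendicular distances
#'
#' Maximizes the conditional likelihood of observed perpendicular distances
#' under a truncated detection-function-shaped density on `[0, w]` (the
#' standard line-transect form: the density is the detection function
#' normalized over the truncation interval, so `g(0)` cancels and is not
#' estimable from distances). The only parameter is the half-normal scale,
#' optimized on the log scale.
#'
#' @param distances perpendicular distances, in `[0, w]`.
#' @param w truncation distance (default 600 m).
#' @param form `"halfnormal"` or `"mixture"` (uniform out to `breakpoint`,
#'   continuous half-normal decline beyond).
#' @param breakpoint photo-reach distance for the mixture form (default 350).
#' @return list with `sigma` (MLE of the scale), `nll`, `AIC = 2 + 2 nll`
#'   (one estimated parameter for either form), `form`, `w`, and
#'   `convergence` diagnostics.
#' @export
fit_distance <- function(distances, w = 600,
                         form = c("halfnormal", "mixture"),
                         breakpoint = 350) {
  form <- match.arg(form)
  if (length(distances) < 2)
    stop("at least two distances are required to fit a detection function")
  if (any(distances < 0) || any(distances > w))
    stop("all distances must lie in [0, w]")
  nll_fun <- function(log_sigma) {
    s <- exp(log_sigma)
    -sum(log(detfun_value(distances, s, form, breakpoint))) +
      length(distances) * log(detfun_integral(s, w, form, breakpoint))
  }
  opt <- stats::optimize(nll_fun, interval = log(c(w * 1e-3, w * 1e3)))
  # guard against an interior optimum hugging the bracket
  grad <- (nll_fun(opt$minimum + 1e-5) - nll_fun(opt$minimum - 1e-5)) / 2e-5
  list(sigma = exp(opt$minimum),
       nll = opt$objective,
       AIC = 2 + 2 * opt$objective,
       form = form, w = w,
       breakpoint = if (form == "mixture") breakpoint else NA_real_,
       convergence = list(gradient = grad, converged = abs(grad) < 1e-2))
}
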