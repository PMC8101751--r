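#' Fraction of a cell's saltwater habitat covered by survey effort
#'
#' For the visual/photographic platform the covered fraction is a fixed
#' 1.2 km strip (0.6 km each side of the trackline) times transect length;
#' for the thermal/photographic platform it is the total ground footprint of
#' the photographs. Either way the fraction is clipped to `[0, 1]`.
#'
#' @param platform `"ru"` (strip) or `"us"` (photo footprint).
#' @param area_sw saltwater habitat area of the cell, km^2 (> 0 when any
#'   effort is recorded).
#' @param length_km transect length in the cell (RU platform).
#' @param footprint_km2 total photo ground footprint in the cell (US
#'   platform).
#' @param strip_km full strip width for the RU platform (default 1.2 km).
#' @return coverage fraction `a` in `[0, 1]`.
#' @export
coverage_fraction <- function(platform = c("ru", "us"), area_sw,
                              length_km = NULL, footprint_km2 = NULL,
                              strip_km = 1.2) {
  platform <- match.arg(platform)
  covered <- switch(platform,
    ru = {
      if (is.null(length_km)) stop("RU coverage needs 'length_km'")
      length_km * strip_km
    },
    us = {
      if (is.null(footprint_km2)) stop("US coverage needs 'footprint_km2'")
      footprint_km2
    })
  if (any(area_sw <= 0 & covered > 0))
    stop("nonzero effort recorded in a cell without saltwater habitat")
  a <- ifelse(covered > 0, covered / area_sw, 0)
  pmin(a, 1)
}

#' Poisson negative log likelihood of thinned group counts
#'
#' Counts of detected bear groups in surveyed cell-days are Poisson with
#' mean `xi * N * pi * p`, where `N` is total group abundance, `pi` the
#' cell-day occupancy probability, `p = theta * a` the compound detection
#' probability, and `xi` a relative-detectability scaling (1 for primary
#' counts; estimated for auxiliary counts).
#'
#' @param counts nonnegative integer counts, one per surveyed cell-day.
#' @param N total number of groups in the study area.
#' @param pi occupancy probabilities aligned with `counts`.
#' @param p compound detection probabilities aligned with `counts`.
#' @param xi relative detectability scaling (default 1).
#' @return scalar negative log likelihood.
#' @export
count_nll <- function(counts, N, pi, p, xi = 1) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(counts > 0 & p <= 0))
    stop("positive count in a cell-day with zero detection probability")
  -sum(stats::dpois(counts, xi * N * pi * p, log = TRUE))
}

#' Shifted (zero-truncated) Poisson group-size likelihood and MLE
#'
#' Observed group sizes `g >= 1` are modeled as `(g - 1) ~ Poisson(mu_g - 1)`,
#' so every group has at least one bear and `mu_g` is the mean group size.
#' The maximum likelihood estimate of `mu_g` is the sample mean.
#'
#' @param g integer group sizes, all `>= 1`.
#' @param mu_g mean group size, `>= 1`.
#' @return `groupsize_nll`: scalar negative log likelihood;
#'   `groupsize_mle`: the MLE of `mu_g` (the sample mean of `g`).
#' @export
groupsize_nll <- function(g, mu_g) {
  if (any(g < 1) || any(g != round(g))) stop("group sizes must be integers >= 1")
  if (mu_g < 1) stop("'mu_g' must be >= 1")
  -sum(stats::dpois(g - 1, mu_g - 1, log = TRUE))
}

#' @rdname groupsize_nll
#' @export
groupsize_mle <- function(g) {
  if (!length(g)) stop("no group sizes supplied")
  if (any(g < 1) || any(g != round(g))) stop("group sizes must be integers >= 1")
  mean(g)
}

#' Conditional likelihood of perpendicular distances
#'
#' Negative log likelihood of observed perpendicular distances under the
#' truncated half-normal line-transect density on `[0, w]`. Conditioning on
#' detection means `g(0)` cancels; it affects only the average detection
#' probability, never the distance density.
#'
#' @param distances perpendicular distances in `[0, w]`.
#' @param sigma half-normal scale.
#' @param w truncation distance.
#' @return scalar negative log likelihood.
#' @export
distance_nll <- function(distances, sigma, w = 600) {
  if (!length(distances)) return(0)
  if (any(distances < 0) || any(distances > w))
    stop("all distances must lie in [0, w]")
  if (sigma <= 0) stop("'sigma' must be positive")
  sum(distances^2) / (2 * sigma^2) +
    length(distances) * log(detfun_integral(sigma, w, "halfnormal", NA))
}

#' Binomial likelihood of the flyover detection trials
#'
#' @param detected,trials trial outcome (`D` of `n` groups detected).
#' @param p_us thermal detection probability.
#' @return scalar negative log likelihood.
#' @export
flyover_nll <- function(detected, trials, p_us) {
  -stats::dbinom(detected, trials, p_us, log = TRUE)
}

#' Assemble the joint model frame
#'
#' Pre-computes everything the joint likelihood needs: design matrices,
#' day-major row indices for every data stream, coverage fractions, smooth
#' bases and penalties, region masks. The same frame drives both the pure-R
#' likelihood ([joint_nll()]) and the Laplace-marginalized fit
#' ([fit_abundance()]).
#'
#' @param survey a `survey_data` list (see [simulate_survey()] /
#'   [read_survey_tables()]).
#' @param grid a `study_grid`.
#' @param cov a `covariate_field` on the same grid.
#' @param g0 fixed trackline detection probability for the RU platform;
#'   must be supplied explicitly (0.6, 0.8 and 1.0 are the conventional
#'   scenarios).
#' @param smooths optional `smooth_spec`; built from `cov` with defaults if
#'   omitted.
#' @param w truncation distance for distance sampling (m, default 600).
#' @param B examined-photograph footprint for the track model (km^2,
#'   default 0.012).
#' @param w99_coef fixed open-water gate coefficient (default -50).
#' @param lambda_shape,lambda_rate Gamma hyperprior for smoothing
#'   parameters (defaults 0.05, 0.005).
#' @return list of class `"abund_frame"`.
#' @export
build_model_frame <- function(survey, grid, cov, g0,
                              smooths = NULL, w = 600, B = 0.012,
                              w99_coef = -50,
                              lambda_shape = 0.05, lambda_rate = 0.005) {
  validate_grid(grid)
  if (missing(g0)) stop("'g0' must be given explicitly (e.g. 0.6, 0.8, 1.0)")
  if (g0 <= 0 || g0 > 1) stop("'g0' must lie in (0, 1]")
  S <- attr(cov, "S"); T_days <- attr(cov, "T_days")
  if (S != nrow(grid)) stop("covariates and grid disagree on cell count")
  if (is.null(smooths)) smooths <- build_smooths(cov)
  A_sw <- saltwater_area(grid)

  idx_of <- function(df) cov_index(cov, df$cell_id, df$day)
  th <- survey$counts_us_thermal
  ax <- survey$counts_us_aux
  ru <- survey$counts_ru
  a_th <- coverage_fraction("us", A_sw[th$cell_id],
                            footprint_km2 = th$footprint_km2)
  a_ax <- coverage_fraction("us", A_sw[ax$cell_id],
                            footprint_km2 = ax$footprint_km2)
  a_ru <- coverage_fraction("ru", A_sw[ru$cell_id], length_km = ru$length_km)
  for (nm in c("counts_us_thermal", "counts_us_aux", "counts_ru")) {
    cc <- survey[[nm]]
    if (any(cc$count < 0 | cc$count != round(cc$count)))
      stop("counts must be nonnegative integers (", nm, ")")
  }
  if (any(th$count > 0 & a_th == 0) || any(ax$count > 0 & a_ax == 0) ||
      any(ru$count > 0 & a_ru == 0))
    stop("positive count recorded in a cell-day with zero coverage")
  dists <- survey$distances$distance_m
  if (length(dists) && (any(dists < 0) || any(dists > w)))
    stop("perpendicular distances must lie in [0, w]")

  structure(list(
    S = S, T_days = T_days, grid = grid, cov = cov,
    A_sw = A_sw, smooths = smooths,
    X_track = build_track_design(cov),
    water99 = cov$water99,
    us_idx = idx_of(survey$tracks_us), us_P = survey$tracks_us$photos,
    us_T = survey$tracks_us$photos_with_tracks,
    ru_idx = idx_of(survey$tracks_ru), ru_L = survey$tracks_ru$length_km,
    ru_T = survey$tracks_ru$tracks,
    th_idx = idx_of(th), th_y = th$count, th_a = a_th,
    ax_idx = idx_of(ax), ax_y = ax$count, ax_a = a_ax,
    cru_idx = idx_of(ru), cru_y = ru$count, cru_a = a_ru,
    distances = dists,
    fly_D = survey$trials$detected, fly_n = survey$trials$trials,
    gsize = survey$groups$size,
    g0 = g0, w = w, B = B, w99_coef = w99_coef,
    lambda_shape = lambda_shape, lambda_rate = lambda_rate,
    regions = region_masks(grid)
  ), class = "abund_frame")
}

# S x R matrix of 0/1 region membership by cell centroid
region_masks <- function(grid) {
  labs <- grep("^region_", names(grid), value = TRUE)
  m <- matrix(0, nrow(grid), length(labs),
              dimnames = list(NULL, sub("^region_", "", labs)))
  for (l in seq_along(labs)) m[, l] <- as.numeric(grid[[labs[l]]])
  cbind(all = 1, m)
}

#' Occupancy, track and abundance surfaces implied by a parameter set
#'
#' Evaluates the linear predictors at the supplied parameters: the latent
#' track intensity surface `Z`, the mean-standardized track covariate, the
#' abundance predictor `nu` (smooths + open-water gate + track effect) and
#' the daily occupancy probabilities `pi`.
#'
#' @param params parameter list (see [joint_nll()]).
#' @param frame an `abund_frame`.
#' @return list with `Z` (vector, day-major), `nu` (vector), and `pi`
#'   (`S x T` matrix with columns summing to 1).
#' @keywords internal
predictor_surfaces <- function(params, frame) {
  Z <- track_intensity(frame$X_track, params$beta)
  Zstd <- Z / mean(Z)
  nu <- drop(frame$smooths$X %*% params$alpha) +
    frame$w99_coef * frame$water99 + params$alpha_tracks * Zstd
  Pi <- matrix(0, frame$S, frame$T_days)
  for (t in seq_len(frame$T_days)) {
    nu_t <- nu[(t - 1) * frame$S + seq_len(frame$S)]
    Pi[, t] <- cell_probs(nu_t, frame$A_sw)
  }
  list(Z = Z, nu = nu, pi = Pi)
}

#' Joint negative log likelihood of all survey data sources
#'
#' The full joint objective: track likelihoods (binomial photo-presence and
#' Poisson observer counts on the common latent intensity), Poisson count
#' likelihoods for thermal, auxiliary and distance-sampled platform counts,
#' the flyover-trial binomial, the conditional distance likelihood, the
#' shifted-Poisson group-size likelihood, and the Gaussian smoothing prior
#' on spline coefficients with Gamma hyperpriors on smoothing parameters.
#' This is the same function of the parameters that the Laplace-marginalized
#' fit optimizes (before integration over the spline coefficients).
#'
#' @param params list with elements `N` (> 0), `alpha` (spline coefficient
#'   vector), `alpha_tracks`, `lambda` (positive, one per smooth), `beta`
#'   (track coefficients, length 6), `eta`, `xi`, `sigma` (all > 0), `p_us`
#'   in `[0, 1]`, and `mu_g >= 1`.
#' @param frame an `abund_frame` from [build_model_frame()].
#' @return scalar negative log likelihood, with a `"parts"` attribute
#'   breaking it into submodel contributions.
#' @export
joint_nll <- function(params, frame) {
  surf <- predictor_surfaces(params, frame)
  Z <- surf$Z; Pi <- as.vector(surf$pi)

  phi <- photo_track_prob(Z[frame$us_idx], frame$B)
  nll_track <-
    -sum(stats::dbinom(frame$us_T, frame$us_P, phi, log = TRUE)) -
    sum(stats::dpois(frame$ru_T, frame$ru_L * params$eta * Z[frame$ru_idx],
                     log = TRUE))

  p_rus <- halfnormal_p(params$sigma, frame$w, frame$g0)
  nll_counts <-
    count_nll(frame$th_y, params$N, Pi[frame$th_idx],
              params$p_us * frame$th_a) +
    count_nll(frame$ax_y, params$N, Pi[frame$ax_idx],
              params$p_us * frame$ax_a, xi = params$xi) +
    count_nll(frame$cru_y, params$N, Pi[frame$cru_idx],
              p_rus * frame$cru_a)

  nll_det <- flyover_nll(frame$fly_D, frame$fly_n, params$p_us) +
    distance_nll(frame$distances, params$sigma, frame$w)
  nll_g <- groupsize_nll(frame$gsize, params$mu_g)
  nll_prior <- alpha_prior_nll(params$alpha, params$lambda, frame$smooths,
                               frame$lambda_shape, frame$lambda_rate)

  total <- nll_track + nll_counts + nll_det + nll_g + nll_prior
  attr(total, "parts") <- c(track = nll_track, counts = nll_counts,
                            detection = nll_det, groupsize = nll_g,
                            prior = nll_prior)
  total
}
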