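#' Design matrix for the latent track-intensity model
#'
#' The log of the latent track intensity is a fixed polynomial regression:
#' intercept, linear and quadratic distance from land (standardized to mean
#' 1), linear and quadratic sea-ice concentration, and a linear RSF effect.
#'
#' @param cov a `covariate_field` from [make_covariates()].
#' @param cell,day optional cell id and day; if supplied, the single row for
#'   that (cell, day) is returned, otherwise the full `S * T` design.
#' @return numeric matrix with columns
#'   `(intercept, d, d^2, ice, ice^2, rsf)` where `d` is standardized
#'   distance from land.
#' @export
build_track_design <- function(cov, cell = NULL, day = NULL) {
  if (!is.null(cell) || !is.null(day)) {
    keep <- cov$cell_id == cell & cov$day == day
    if (!any(keep))
      stop(sprintf("no covariates for cell %s on day %s", cell, day))
    cov <- cov[keep, , drop = FALSE]
  }
  if (anyNA(cov$ice) || anyNA(cov$dist_land_std) || anyNA(cov$rsf)) {
    bad <- which(is.na(cov$ice) | is.na(cov$dist_land_std) | is.na(cov$rsf))[1]
    stop(sprintf("missing covariate value for cell %d on day %d",
                 cov$cell_id[bad], cov$day[bad]))
  }
  d <- cov$dist_land_std
  X <- cbind(intercept = 1, d = d, d2 = d^2,
             ice = cov$ice, ice2 = cov$ice^2, rsf = cov$rsf)
  rownames(X) <- NULL
  X
}

#' Latent track intensity
#'
#' Expected number of track features per km^2 in a cell-day under the
#' "blocky" Poisson point-process approximation, `Z = exp(x'beta)`.
#'
#' @param x design row(s) from [build_track_design()].
#' @param beta coefficient vector (length 6).
#' @return nonnegative intensity (tracks per km^2), one value per row of `x`.
#' @export
track_intensity <- function(x, beta) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(beta))
    stop("design and coefficient dimensions disagree")
  exp(drop(x %*% beta))
}

#' Probability that a photograph contains at least one track
#'
#' Under a Poisson track process with intensity `Z`, a photograph with
#' ground footprint `B` km^2 contains one or more tracks with probability
#' `phi = 1 - exp(-B * Z)`.
#'
#' @param Z track intensity (tracks per km^2), nonnegative.
#' @param B photo footprint area in km^2; the default 0.012 is the average
#'   ground footprint of an examined survey photograph.
#' @return probability in `[0, 1]`.
#' @export
photo_track_prob <- function(Z, B = 0.012) {
  if (any(Z < 0)) stop("track intensity 'Z' must be nonnegative")
  if (any(B <= 0)) stop("photo footprint 'B' must be positive")
  -expm1(-B * Z)
}

#' Negative log likelihood of the joint track submodel
#'
#' Joins the two track data streams on the common intensity scale `Z`:
#' the number of examined photographs containing tracks is binomial with
#' success probability `1 - exp(-B Z)`, and observer track counts are
#' Poisson with mean `L * eta * Z`, where the scaling `eta` absorbs the
#' unknown effective strip width for tracks and the delineation of distinct
#' tracks by observers.
#'
#' @param data list with elements `us` (data.frame: `cell_id`, `day`,
#'   `photos`, `photos_with_tracks`) and `ru` (data.frame: `cell_id`, `day`,
#'   `length_km`, `tracks`). Either element may be `NULL` or empty.
#' @param params list with `beta` (length-6 coefficient vector), `eta`
#'   (positive scaling) and optionally `B` (photo footprint, default 0.012).
#' @param cov a `covariate_field`.
#' @return scalar negative log likelihood.
#' @export
track_nll <- function(data, params, cov) {
  beta <- params$beta
  eta <- params$eta
  B <- if (is.null(params$B)) 0.012 else params$B
  if (eta <= 0) stop("'eta' must be positive")
  nll <- 0
  if (!is.null(data$us) && nrow(data$us)) {
    us <- data$us
    if (any(us$photos_with_tracks < 0) ||
        any(us$photos_with_tracks > us$photos))
      stop("photos_with_tracks must lie in [0, photos]")
    X <- design_rows(cov, us$cell_id, us$day, build_track_design)
    phi <- photo_track_prob(track_intensity(X, beta), B)
    nll <- nll - sum(stats::dbinom(us$photos_with_tracks, us$photos,
                                   phi, log = TRUE))
  }
  if (!is.null(data$ru) && nrow(data$ru)) {
    ru <- data$ru
    if (any(ru$tracks < 0) || any(ru$tracks != round(ru$tracks)))
      stop("observer track counts must be nonnegative integers")
    if (any(ru$length_km < 0)) stop("transect lengths must be nonnegative")
    X <- design_rows(cov, ru$cell_id, ru$day, build_track_design)
    Z <- track_intensity(X, beta)
    nll <- nll - sum(stats::dpois(ru$tracks, ru$length_km * eta * Z,
                                  log = TRUE))
  }
  nll
}

# extract design rows for (cell, day) pairs via the day-major cov ordering
design_rows <- function(cov, cell_id, day, builder) {
  S <- attr(cov, "S")
  idx <- (day - 1L) * S + cell_id
  bad <- idx < 1 | idx > nrow(cov) | cov$cell_id[idx] != cell_id |
    cov$day[idx] != day
  if (any(bad)) {
    b <- which(bad)[1]
    stop(sprintf("no covariates for cell %s on day %s", cell_id[b], day[b]))
  }
  builder(cov)[idx, , drop = FALSE]
}

# day-major row index into a covariate_field for (cell, day) pairs
cov_index <- function(cov, cell_id, day) {
  S <- attr(cov, "S")
  (day - 1L) * S + cell_id
}
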