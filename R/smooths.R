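#' Build penalized cubic-spline smooths for the abundance predictor
#'
#' Constructs, for each abundance covariate, a cubic regression spline basis
#' with maximum basis dimension `k` (knots at covariate quantiles) and its
#' integrated-squared-second-derivative penalty matrix, using
#' [mgcv::smoothCon()]. The sum-to-zero identifiability constraint is
#' absorbed into each basis (so every smooth has `k - 1` columns and its
#' penalty a one-dimensional unpenalized null space), matching the
#' generalized-additive construction the abundance model penalizes through
#' Gaussian priors on the coefficients.
#'
#' @param cov a `covariate_field`.
#' @param k maximum basis dimension per covariate (default 6).
#' @param covariates names of `cov` columns to smooth; defaults to sea-ice
#'   concentration, RSF, standardized easting/northing and standardized
#'   distance from land.
#' @param collinear_threshold if the correlation between the standardized
#'   distance-from-land and northing covariates exceeds this value (default
#'   0.9), the distance-from-land smooth is dropped: near-duplicate smooths
#'   leave a flat, unpenalized direction in the coefficient space and the
#'   Laplace approximation degenerates. (Surveys where the coastline is not
#'   an east-west edge keep both smooths.)
#' @return list of class `"smooth_spec"` with elements `X` (row-bound basis,
#'   `nrow(cov)` x `p`), `blocks` (column index per smooth), `S` (list of
#'   penalty matrices), `rank` (penalty ranks), `logdet` (log
#'   pseudo-determinants over the penalized subspace), `labels`, and the
#'   underlying `mgcv` smooth objects (for prediction at new covariate
#'   values).
#' @export
build_smooths <- function(cov, k = 6,
                          covariates = c("ice", "rsf", "easting_std",
                                         "northing_std", "dist_land_std"),
                          collinear_threshold = 0.9) {
  miss <- setdiff(covariates, names(cov))
  if (length(miss))
    stop("covariates not present: ", paste(miss, collapse = ", "))
  if (all(c("dist_land_std", "northing_std") %in% covariates) &&
      abs(stats::cor(cov$dist_land_std, cov$northing_std)) >
        collinear_threshold) {
    message("dist_land smooth dropped: |cor(dist_land, northing)| > ",
            collinear_threshold)
    covariates <- setdiff(covariates, "dist_land_std")
  }
  X_list <- list(); S_list <- list(); sm_list <- list()
  for (v in covariates) {
    if (length(unique(cov[[v]])) < k)
      stop(sprintf(paste0("covariate '%s' has too few distinct values for a ",
                          "k=%d smooth; remove it from the smooth set"), v, k))
    sm <- mgcv::smoothCon(
      eval(parse(text = sprintf("mgcv::s(%s, k = %d, bs = 'cr')", v, k))),
      data = cov, knots = NULL, absorb.cons = TRUE)[[1]]
    X_list[[v]] <- sm$X
    S_list[[v]] <- sm$S[[1]]
    sm_list[[v]] <- sm
  }
  if (!length(covariates)) {
    return(structure(list(X = matrix(0, nrow(cov), 0), blocks = integer(0),
                          S = list(), rank = numeric(0), logdet = numeric(0),
                          labels = character(0), k = k, smooths = list()),
                     class = "smooth_spec"))
  }
  p_each <- vapply(X_list, ncol, integer(1))
  blocks <- rep(seq_along(covariates), times = p_each)
  rank <- numeric(length(S_list)); logdet <- numeric(length(S_list))
  for (i in seq_along(S_list)) {
    ev <- eigen(S_list[[i]], symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-10
    rank[i] <- sum(pos)
    logdet[i] <- sum(log(ev[pos]))
  }
  structure(list(X = do.call(cbind, X_list), blocks = blocks,
                 S = S_list, rank = rank, logdet = logdet,
                 labels = covariates, k = k, smooths = sm_list),
            class = "smooth_spec")
}

#' @export
print.smooth_spec <- function(x, ...) {
  cat("Penalized spline specification:", length(x$S), "smooths\n")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  s(%s): %d basis columns, penalty rank %d\n",
                x$labels[i], sum(x$blocks == i), x$rank[i]))
  }
  invisible(x)
}

# evaluate the centered bases of a smooth_spec at new covariate values
predict_smooths <- function(spec, newdata) {
  do.call(cbind, lapply(spec$smooths, mgcv::PredictMat, data = newdata))
}

#' Cell occupancy probabilities through the area-weighted multinomial link
#'
#' Converts a linear predictor into the probability that a bear group
#' occupies each grid cell on a given day:
#' `pi_s = A_s exp(nu_s) / sum_s' A_s' exp(nu_s')`, where `A_s` is the
#' saltwater habitat of cell `s`. Cells without saltwater habitat get
#' probability zero. The predictor carries no intercept (the softmax is
#' invariant to one).
#'
#' @param nu linear predictor values, one per cell (a single day).
#' @param A saltwater areas (or proportions) per cell, nonnegative.
#' @return probability vector summing to 1.
#' @export
cell_probs <- function(nu, A) {
  if (length(nu) != length(A)) stop("'nu' and 'A' lengths differ")
  if (all(A <= 0)) stop("at least one cell must have saltwater habitat")
  lw <- ifelse(A > 0, log(A) + nu, -Inf)
  m <- max(lw)
  w <- exp(lw - m)
  w / sum(w)
}

#' Gaussian smoothing prior on spline coefficients, with Gamma hyperpriors
#'
#' Negative log density of the coefficient vector under the blockwise
#' Gaussian smoothing prior with precision `lambda_i S_i` per smooth
#' (rank-deficient penalties contribute through their pseudo-determinant
#' over the penalized subspace; the null space is left unpenalized), plus
#' negative log Gamma(shape 0.05, rate 0.005) densities for the smoothing
#' parameters themselves.
#'
#' @param alpha coefficient vector (all smooths, concatenated).
#' @param lambda positive smoothing parameters, one per smooth.
#' @param spec a `smooth_spec` from [build_smooths()].
#' @param shape,rate Gamma hyperprior for each `lambda` (defaults 0.05 and
#'   0.005, mean 10).
#' @return scalar negative log density (coefficient prior + lambda prior).
#' @export
alpha_prior_nll <- function(alpha, lambda, spec, shape = 0.05, rate = 0.005) {
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  if (length(lambda) != length(spec$S))
    stop("one lambda per smooth is required")
  if (length(alpha) != ncol(spec$X))
    stop("'alpha' length does not match the basis dimension")
  nll <- 0
  for (i in seq_along(spec$S)) {
    a_i <- alpha[spec$blocks == i]
    quad <- drop(a_i %*% spec$S[[i]] %*% a_i)
    nll <- nll + 0.5 * lambda[i] * quad -
      0.5 * (spec$rank[i] * log(lambda[i]) + spec$logdet[i]) +
      0.5 * spec$rank[i] * log(2 * pi)
  }
  nll - sum(stats::dgamma(lambda, shape = shape, rate = rate, log = TRUE))
}
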