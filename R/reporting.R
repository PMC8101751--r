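#' Predicted abundance surface
#'
#' Expected number of bears per cell and day implied by a fit:
#' `N_hat_{s,t} = N_hat * pi_hat_{s,t} * mu_g_hat`. Every day's total equals
#' total absolute abundance (the closed population merely redistributes).
#'
#' @param fit an `abund_fit`.
#' @return `S x T` matrix of expected bears per cell-day.
#' @export
abundance_surface <- function(fit) {
  fit$N[["Estimate"]] * fit$pi_hat * fit$mu_g[["Estimate"]]
}

#' Time-averaged abundance within a region
#'
#' Mean over survey days of the summed abundance surface across cells whose
#' centroids fall inside the region. For the full grid this equals total
#' absolute abundance exactly.
#'
#' @param surface `S x T` abundance surface from [abundance_surface()].
#' @param grid the `study_grid` the surface lives on.
#' @param region region label: `"all"` or one of the grid's flags
#'   (`"us"`, `"ru"`, `"pbsg"`, `"regehr"`).
#' @return scalar time-averaged abundance.
#' @export
region_abundance <- function(surface, grid, region = "all") {
  masks <- region_masks(grid)
  if (!region %in% colnames(masks))
    stop("unknown region label '", region, "'; available: ",
         paste(colnames(masks), collapse = ", "))
  mean(colSums(surface * masks[, region]))
}

#' Bears per square kilometre of sea-ice habitat
#'
#' @param N_star absolute abundance.
#' @param ice_area_km2 sea-ice habitat area (km^2), e.g. from
#'   [ice_area_series()]; must be positive.
#' @return density in bears per km^2.
#' @export
density_per_ice <- function(N_star, ice_area_km2) {
  if (any(ice_area_km2 <= 0)) stop("ice area must be positive")
  N_star / ice_area_km2
}

#' Daily sea-ice habitat area
#'
#' Concentration-weighted saltwater area summed over cells,
#' `ice_t = sum_s ice_{s,t} A_s`, in km^2.
#'
#' @param cov a `covariate_field`.
#' @param grid the matching `study_grid`.
#' @return numeric vector, one value per survey day.
#' @export
ice_area_series <- function(cov, grid) {
  A_sw <- saltwater_area(grid)
  S <- attr(cov, "S"); T_days <- attr(cov, "T_days")
  vapply(seq_len(T_days), function(t) {
    sum(cov$ice[(t - 1) * S + seq_len(S)] * A_sw)
  }, numeric(1))
}

#' Pearson correlation between two cell-day surfaces
#'
#' Used to compare, e.g., the estimated track-intensity surface with the
#' estimated bear density surface across all cell-days.
#'
#' @param surface_a,surface_b matrices (or vectors) of matching shape.
#' @return Pearson correlation coefficient.
#' @export
surface_correlation <- function(surface_a, surface_b) {
  a <- as.vector(surface_a); b <- as.vector(surface_b)
  if (length(a) != length(b)) stop("surfaces have different shapes")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("cannot correlate a constant surface")
  stats::cor(a, b)
}
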