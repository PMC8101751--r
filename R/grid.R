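#' Build a planar equal-area survey grid
#'
#' Constructs a regular lattice of square cells on a planar equal-area
#' convention, emulating the ~25 km x 25 km survey grid used for springtime
#' aerial surveys over sea ice. Land is placed along the southern lattice
#' boundary; cells adjacent to it receive a reduced saltwater proportion so
#' that the coastal density gradient the abundance model cares about has
#' something to act on. Region membership flags split the grid into an
#' eastern ("US") and a western ("RU") half, with two nested sub-rectangles
#' ("PBSG", "Regehr") analogous to the management and capture-recapture
#' study boundaries used when reporting regional abundance.
#'
#' @param nx,ny number of cells in the easting / northing direction.
#' @param cell_km side length of a cell (km); the default mirrors the 25 km
#'   resolution of the sea-ice concentration product the survey grid was
#'   aligned to.
#' @param seed integer seed; the same seed always yields an identical grid.
#'
#' @return A `data.frame` of class `"study_grid"` with one row per cell and
#'   columns `cell_id`, `easting`, `northing` (cell centroids, km), `area`
#'   (total cell area, km^2), `saltwater_prop` (fraction of the cell that is
#'   saltwater habitat, in `[0, 1]`), and logical region flags `region_us`,
#'   `region_ru`, `region_pbsg`, `region_regehr`.
#' @examples
#' g <- make_grid(4, 4, cell_km = 25, seed = 1)
#' sum(g$area)
#' @export
make_grid <- function(nx, ny, cell_km = 25, seed = 1L) {
  if (length(nx) != 1L || length(ny) != 1L || nx < 1 || ny < 1)
    stop("grid dimensions 'nx' and 'ny' must be positive integers")
  if (cell_km <= 0) stop("'cell_km' must be positive")
  nx <- as.integer(nx); ny <- as.integer(ny)

  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  easting <- (col - 0.5) * cell_km
  northing <- (row - 0.5) * cell_km

  # coastal saltwater gradient: land along the southern lattice edge
  sw <- 1 - exp(-northing / (0.8 * cell_km))
  rng <- local_rng(seed)
  jitter <- rng$runif(nx * ny, -0.08, 0.08)
  sw <- pmin(1, pmax(0, ifelse(sw < 0.99, sw + jitter, sw)))

  e_max <- nx * cell_km
  n_max <- ny * cell_km
  region_us <- easting > e_max / 2
  region_pbsg <- easting > 0.05 * e_max & easting < 0.95 * e_max &
    northing < 0.85 * n_max
  region_regehr <- easting > 0.70 * e_max & easting < 0.95 * e_max &
    northing > 0.05 * n_max & northing < 0.35 * n_max

  grid <- data.frame(
    cell_id = seq_len(nx * ny),
    easting = easting,
    northing = northing,
    area = cell_km^2,
    saltwater_prop = sw,
    region_us = region_us,
    region_ru = !region_us,
    region_pbsg = region_pbsg,
    region_regehr = region_regehr
  )
  attr(grid, "nx") <- nx
  attr(grid, "ny") <- ny
  attr(grid, "cell_km") <- cell_km
  class(grid) <- c("study_grid", "data.frame")
  validate_grid(grid)
  grid
}

validate_grid <- function(grid) {
  stopifnot(is.data.frame(grid))
  need <- c("cell_id", "easting", "northing", "area", "saltwater_prop")
  miss <- setdiff(need, names(grid))
  if (length(miss))
    stop("grid is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(grid$cell_id)) stop("cell_id values must be unique")
  if (any(grid$area <= 0)) stop("cell areas must be positive")
  if (any(grid$saltwater_prop < 0 | grid$saltwater_prop > 1))
    stop("saltwater_prop must lie in [0, 1]")
  invisible(grid)
}

#' Saltwater habitat area of each grid cell
#'
#' @param grid a `study_grid`.
#' @return numeric vector, km^2 of saltwater habitat per cell
#'   (total area times saltwater proportion).
#' @export
saltwater_area <- function(grid) {
  grid$area * grid$saltwater_prop
}

#' Generate spatio-temporal covariate fields for a survey grid
#'
#' Simulates the covariates the track and abundance models use: daily sea-ice
#' concentration declining in expectation through the survey (southern,
#' near-coast cells melt first), a static relative-use (RSF) surface built
#' from smooth radial bumps, distance to land, and standardized coordinates.
#' The open-water indicator `water99` flags cells whose ice concentration is
#' below 1%. Optionally a fraction of ice values is deleted and refilled by
#' inverse-distance interpolation, emulating the unreliable near-coast cells
#' of the remotely sensed ice product.
#'
#' Distance to land, easting and northing are standardized by division by
#' their grand means, so each standardized covariate has mean 1.
#'
#' @param grid a `study_grid` from [make_grid()].
#' @param T_days number of survey days.
#' @param seed integer seed.
#' @param missing_frac fraction of (cell, day) ice values deleted and then
#'   interpolated (default 0).
#'
#' @return A `data.frame` of class `"covariate_field"` with `S * T_days`
#'   rows ordered day-major (all cells for day 1, then day 2, ...), and
#'   columns `cell_id`, `day`, `ice`, `water99`, `dist_land`, `rsf`,
#'   `easting_std`, `northing_std`, `dist_land_std`.
#' @export
make_covariates <- function(grid, T_days, seed = 1L, missing_frac = 0) {
  validate_grid(grid)
  if (length(T_days) != 1L || T_days < 1) stop("'T_days' must be >= 1")
  T_days <- as.integer(T_days)
  rng <- local_rng(seed)
  S <- nrow(grid)
  e_max <- max(grid$easting); n_max <- max(grid$northing)

  # land is the southern lattice edge; distance from centroid to that edge
  dist_land <- grid$northing

  # static RSF surface: sum of smooth radial bumps, normalized to mean 1
  rsf <- radial_bump_field(grid$easting, grid$northing, n_bumps = 4,
                           scale = 0.35 * max(e_max, n_max), rng = rng)
  rsf <- rsf / mean(rsf)

  # latent ice field: spatial base minus a melt forcing that grows with day
  # and is strongest in southern (near-land) cells
  base <- 2.6 + 1.1 * radial_bump_field(grid$easting, grid$northing,
                                        n_bumps = 3,
                                        scale = 0.45 * max(e_max, n_max),
                                        rng = rng, center = TRUE)
  melt_sus <- exp(-dist_land / (0.45 * n_max))    # southern cells melt first
  melt_force <- seq(0, 9, length.out = max(T_days, 2L))[seq_len(T_days)]

  ice <- matrix(NA_real_, S, T_days)
  for (t in seq_len(T_days)) {
    ice[, t] <- stats::plogis(base - melt_force[t] * melt_sus)
  }

  if (missing_frac > 0) {
    n_miss <- floor(missing_frac * S * T_days)
    miss <- rng$sample(S * T_days, n_miss)
    ice[miss] <- NA_real_
    for (t in seq_len(T_days)) {
      ice[, t] <- idw_fill(ice[, t], grid$easting, grid$northing)
    }
  }

  cov <- data.frame(
    cell_id = rep(grid$cell_id, times = T_days),
    day = rep(seq_len(T_days), each = S),
    ice = as.vector(ice),
    dist_land = rep(dist_land, times = T_days),
    rsf = rep(rsf, times = T_days),
    easting_std = rep(grid$easting / mean(grid$easting), times = T_days),
    northing_std = rep(grid$northing / mean(grid$northing), times = T_days),
    dist_land_std = rep(dist_land / mean(dist_land), times = T_days)
  )
  cov$water99 <- as.integer(cov$ice < 0.01)
  attr(cov, "S") <- S
  attr(cov, "T_days") <- T_days
  class(cov) <- c("covariate_field", "data.frame")
  cov
}

#' Inverse-distance-weighted fill of missing values on a point set
#'
#' Fills `NA` entries of `values` by inverse-distance weighting (power 2)
#' over the `k` nearest non-missing neighbors. A documented stand-in for
#' kriging of unreliable near-coast ice cells.
#'
#' @param values numeric vector with possible `NA`s.
#' @param x,y point coordinates.
#' @param k number of neighbors (default 8).
#' @param power inverse-distance power (default 2).
#' @return `values` with `NA`s replaced.
#' @export
idw_fill <- function(values, x, y, k = 8, power = 2) {
  miss <- which(is.na(values))
  if (!length(miss)) return(values)
  obs <- which(!is.na(values))
  if (!length(obs)) stop("cannot interpolate: all values missing")
  out <- values
  for (i in miss) {
    d2 <- (x[obs] - x[i])^2 + (y[obs] - y[i])^2
    nb <- obs[order(d2)[seq_len(min(k, length(obs)))]]
    dd <- sqrt((x[nb] - x[i])^2 + (y[nb] - y[i])^2)
    if (any(dd == 0)) {
      out[i] <- mean(values[nb[dd == 0]])
    } else {
      wgt <- 1 / dd^power
      out[i] <- sum(wgt * values[nb]) / sum(wgt)
    }
  }
  out
}

# smooth positive field as a sum of radial Gaussian bumps
radial_bump_field <- function(x, y, n_bumps, scale, rng,
                              center = FALSE) {
  cx <- rng$runif(n_bumps, min(x), max(x))
  cy <- rng$runif(n_bumps, min(y), max(y))
  amp <- rng$runif(n_bumps, 0.5, 1.5)
  f <- numeric(length(x))
  for (b in seq_len(n_bumps)) {
    f <- f + amp[b] * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * scale^2))
  }
  if (center) f <- f - mean(f)
  f
}

# Seed-local RNG: draws are reproducible for a given seed and never disturb
# (or depend on) the caller's global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  run <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      on.exit({
        assign("state", get(".Random.seed", globalenv()), envir = env)
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      })
      if (is.null(env$state)) {
        set.seed(seed)
      } else assign(".Random.seed", env$state, envir = globalenv())
      fn(...)
    }
  }
  list(
    runif = run(stats::runif),
    rpois = run(stats::rpois),
    rbinom = run(stats::rbinom),
    rmultinom = run(stats::rmultinom),
    rnorm = run(stats::rnorm),
    sample = run(function(n, size) sample.int(n, size))
  )
}
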