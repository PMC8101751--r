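#' Define a synthetic survey scenario
#'
#' Bundles the generating parameters and effort layout for the synthetic
#' survey generator. Defaults describe a springtime sea-ice survey at desk
#' scale: a 20 x 20 grid of 25 km cells surveyed over 10 days by two
#' platforms flying parallel row transects, 600 bear groups of mean size
#' 1.4 redistributing daily, a thermal detection probability of 0.67
#' assessed by 12 flyover trials, and half-normal visual detection with
#' scale 250 m truncated at 600 m.
#'
#' @param S number of grid cells (must be `nx * ny` of the grid used).
#' @param T_days number of survey days.
#' @param true_N number of bear groups present (closed population).
#' @param true_mu_g mean group size (`>= 1`).
#' @param true_beta track-model coefficients
#'   `(intercept, d, d^2, ice, ice^2, rsf)` on the log-intensity scale.
#' @param true_alpha_cov abundance-predictor coefficients for
#'   `(ice, rsf, northing_std, easting_std)` used by the generator's
#'   log-linear truth; the negative easting default concentrates bears in
#'   the western half of the study area, as observed.
#' @param true_alpha_tracks track-covariate effect in the abundance
#'   predictor (0: tracks carry no information beyond the habitat
#'   covariates).
#' @param true_eta observer track-count scaling (tracks per km per unit
#'   intensity).
#' @param true_xi relative detectability of auxiliary visual counts.
#' @param true_sigma half-normal detection scale (m).
#' @param true_p_us thermal detection probability.
#' @param g0 trackline detection probability used when generating
#'   (and later fitting) the distance-sampled platform.
#' @param w truncation distance (m).
#' @param breakpoint photo-reach distance (m), kept with the scenario for
#'   mixture-form comparisons.
#' @param n_trials number of flyover trials.
#' @param transects_per_day column transects (flown perpendicular to the
#'   coast, so each crosses the full density gradient) per platform per
#'   day.
#' @param photos_per_km examined photographs per km of transect (not fixed
#'   by any survey record; a free effort knob).
#' @param us_swath_km photographic swath width (km) determining the ground
#'   footprint of the thermal/photo platform.
#' @param seed integer seed; fully determines the generated survey.
#' @return list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(S = 400, T_days = 10, true_N = 600,
                         true_mu_g = 1.4,
                         true_beta = c(0.5, -1.2, 0.15, 2.0, -0.5, 0.4),
                         true_alpha_cov = c(ice = 2.0, rsf = 0.8,
                                            northing_std = -0.8,
                                            easting_std = -0.8),
                         true_alpha_tracks = 0,
                         true_eta = 0.05, true_xi = 1.67,
                         true_sigma = 250, true_p_us = 0.67,
                         g0 = 1, w = 600, breakpoint = 350,
                         n_trials = 12, transects_per_day = 4,
                         photos_per_km = 1.4, us_swath_km = 0.37,
                         seed = 1L) {
  sc <- list(S = S, T_days = T_days, true_N = true_N, true_mu_g = true_mu_g,
             true_beta = true_beta, true_alpha_cov = true_alpha_cov,
             true_alpha_tracks = true_alpha_tracks, true_eta = true_eta,
             true_xi = true_xi, true_sigma = true_sigma,
             true_p_us = true_p_us, g0 = g0, w = w, breakpoint = breakpoint,
             n_trials = n_trials, transects_per_day = transects_per_day,
             photos_per_km = photos_per_km, us_swath_km = us_swath_km,
             seed = as.integer(seed))
  stopifnot(sc$true_N >= 0, sc$true_mu_g >= 1, sc$true_eta > 0,
            sc$true_xi > 0, sc$true_sigma > 0,
            sc$true_p_us >= 0, sc$true_p_us <= 1,
            sc$g0 > 0, sc$g0 <= 1, sc$w > 0,
            sc$breakpoint > 0, sc$breakpoint < sc$w)
  class(sc) <- "sim_scenario"
  sc
}

# generator's true occupancy surface: log-linear habitat preference plus the
# open-water gate, through the same area-weighted multinomial link the
# estimator uses
true_occupancy <- function(grid, cov, scenario) {
  a <- scenario$true_alpha_cov
  nu <- a[["ice"]] * cov$ice + a[["rsf"]] * cov$rsf +
    a[["northing_std"]] * cov$northing_std +
    a[["easting_std"]] * cov$easting_std - 50 * cov$water99
  if (scenario$true_alpha_tracks != 0) {
    Z <- track_intensity(build_track_design(cov), scenario$true_beta)
    nu <- nu + scenario$true_alpha_tracks * Z / mean(Z)
  }
  S <- attr(cov, "S"); T_days <- attr(cov, "T_days")
  A_sw <- saltwater_area(grid)
  Pi <- matrix(0, S, T_days)
  for (t in seq_len(T_days)) {
    Pi[, t] <- cell_probs(nu[(t - 1) * S + seq_len(S)], A_sw)
  }
  Pi
}

# effort layout: each platform flies parallel column transects
# (perpendicular to the coast) across its half of the grid; columns cycle
# through a seeded permutation so effort is spread over space
# ("space-filling") as in the survey's design philosophy
effort_layout <- function(grid, scenario, rng) {
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  cell_km <- attr(grid, "cell_km")
  T_days <- scenario$T_days
  cols_of <- function(flag) {
    sort(unique(grid$easting[flag]))
  }
  col_seq <- function(cols) {
    perm <- cols[rng$sample(length(cols), length(cols))]
    matrix(rep(perm, length.out = T_days * scenario$transects_per_day),
           nrow = scenario$transects_per_day)
  }
  ru_cols <- col_seq(cols_of(grid$region_ru))
  us_cols <- col_seq(cols_of(grid$region_us))
  out <- list()
  for (t in seq_len(T_days)) {
    for (platform in c("ru", "us")) {
      cols <- unique(if (platform == "ru") ru_cols[, t] else us_cols[, t])
      for (e in cols) {
        cells <- grid$cell_id[grid$easting == e]
        if (length(cells))
          out[[length(out) + 1L]] <- data.frame(
            platform = platform, day = t, cell_id = cells,
            length_km = cell_km)
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a dual-platform aerial survey
#'
#' Draws every data stream the joint model consumes, from known parameters:
#' latent track intensities and the two track data types, daily multinomial
#' redistribution of a closed population of groups, Poisson-thinned counts
#' for thermal, auxiliary and distance-sampled platforms, perpendicular
#' distances from the truncated half-normal, shifted-Poisson group sizes,
#' and binomial flyover trials. Counts are drawn with the exact means the
#' estimator assumes (`Poisson(xi N pi p)`), so the generator is a faithful
#' mirror of the fitted model; the realized group placements are also
#' returned for conservation checks.
#'
#' @param grid a `study_grid` whose cell count matches `scenario$S`.
#' @param cov a `covariate_field` for `scenario$T_days` days.
#' @param scenario a `sim_scenario`.
#' @return list of class `"survey_data"` with elements `tracks_us`,
#'   `tracks_ru`, `counts_us_thermal`, `counts_us_aux`, `counts_ru`,
#'   `distances`, `trials`, `groups`, `effort`, plus a `truth` element
#'   (true `pi`, `Z`, realized placements, expected count totals and the
#'   scenario) for use in tests and calibration studies.
#' @export
simulate_survey <- function(grid, cov, scenario) {
  validate_grid(grid)
  if (nrow(grid) != scenario$S)
    stop("grid size does not match scenario$S")
  if (attr(cov, "T_days") != scenario$T_days)
    stop("covariate days do not match scenario$T_days")
  rng <- local_rng(scenario$seed + 1000L)
  S <- scenario$S; T_days <- scenario$T_days
  A_sw <- saltwater_area(grid)

  X <- build_track_design(cov)
  Z <- track_intensity(X, scenario$true_beta)
  Pi <- true_occupancy(grid, cov, scenario)

  # realized daily placements of the closed population (fresh multinomial
  # redistribution each day; no movement kernel)
  placements <- matrix(0L, S, T_days)
  if (scenario$true_N > 0) {
    for (t in seq_len(T_days)) {
      placements[, t] <- as.integer(rng$rmultinom(1, scenario$true_N, Pi[, t]))
    }
  }

  eff <- effort_layout(grid, scenario, rng)
  idx <- (eff$day - 1L) * S + eff$cell_id
  p_rus <- halfnormal_p(scenario$true_sigma, scenario$w, scenario$g0)

  us <- eff[eff$platform == "us", ]
  ru <- eff[eff$platform == "ru", ]
  us_idx <- (us$day - 1L) * S + us$cell_id
  ru_idx <- (ru$day - 1L) * S + ru$cell_id

  # track data
  P_photos <- floor(scenario$photos_per_km * us$length_km)
  phi <- photo_track_prob(Z[us_idx], 0.012)
  tracks_us <- data.frame(cell_id = us$cell_id, day = us$day,
                          photos = P_photos,
                          photos_with_tracks = rng$rbinom(nrow(us),
                                                          P_photos, phi))
  tracks_ru <- data.frame(cell_id = ru$cell_id, day = ru$day,
                          length_km = ru$length_km,
                          tracks = rng$rpois(nrow(ru),
                                             ru$length_km * scenario$true_eta *
                                               Z[ru_idx]))

  # counts: Poisson thinning with the model's own means
  footprint <- us$length_km * scenario$us_swath_km
  a_us <- coverage_fraction("us", A_sw[us$cell_id], footprint_km2 = footprint)
  a_ru <- coverage_fraction("ru", A_sw[ru$cell_id], length_km = ru$length_km)
  mu_th <- scenario$true_N * Pi[cbind(us$cell_id, us$day)] *
    scenario$true_p_us * a_us
  mu_ax <- scenario$true_xi * mu_th
  mu_ru <- scenario$true_N * Pi[cbind(ru$cell_id, ru$day)] * p_rus * a_ru

  counts_us_thermal <- data.frame(cell_id = us$cell_id, day = us$day,
                                  count = rng$rpois(nrow(us), mu_th),
                                  footprint_km2 = footprint)
  counts_us_aux <- data.frame(cell_id = us$cell_id, day = us$day,
                              count = rng$rpois(nrow(us), mu_ax),
                              footprint_km2 = footprint)
  counts_ru <- data.frame(cell_id = ru$cell_id, day = ru$day,
                          count = rng$rpois(nrow(ru), mu_ru),
                          length_km = ru$length_km)

  # perpendicular distances for every distance-sampled detection: density
  # proportional to the half-normal detection function on [0, w] (the
  # constant g(0) thinning does not change the detected-distance density)
  n_det_ru <- sum(counts_ru$count)
  dist_m <- if (n_det_ru > 0) {
    u <- rng$runif(n_det_ru, 0, 1)
    Phi_w <- stats::pnorm(scenario$w / scenario$true_sigma)
    scenario$true_sigma * stats::qnorm(0.5 + u * (Phi_w - 0.5))
  } else numeric(0)
  distances <- data.frame(
    cell_id = rep(counts_ru$cell_id, counts_ru$count),
    day = rep(counts_ru$day, counts_ru$count),
    distance_m = dist_m)

  # group sizes for every detected group, any platform
  n_groups <- sum(counts_us_thermal$count) + sum(counts_us_aux$count) +
    n_det_ru
  groups <- data.frame(
    group_id = seq_len(n_groups),
    platform = rep(c("us", "us_aux", "ru"),
                   c(sum(counts_us_thermal$count), sum(counts_us_aux$count),
                     n_det_ru)),
    size = 1L + rng$rpois(n_groups, scenario$true_mu_g - 1))

  trials <- data.frame(detected = rng$rbinom(1, scenario$n_trials,
                                             scenario$true_p_us),
                       trials = scenario$n_trials)

  structure(list(
    tracks_us = tracks_us, tracks_ru = tracks_ru,
    counts_us_thermal = counts_us_thermal, counts_us_aux = counts_us_aux,
    counts_ru = counts_ru, distances = distances, trials = trials,
    groups = groups, effort = eff,
    truth = list(pi = Pi, Z = Z, placements = placements,
                 expected_counts = c(thermal = sum(mu_th), aux = sum(mu_ax),
                                     ru = sum(mu_ru)),
                 p_rus = p_rus, scenario = scenario)
  ), class = "survey_data")
}

#' @export
print.survey_data <- function(x, ...) {
  cat("Dual-platform survey data\n")
  cat(sprintf("  track rows: %d photo (us), %d observer (ru)\n",
              nrow(x$tracks_us), nrow(x$tracks_ru)))
  cat(sprintf("  surveyed cell-days: %d thermal, %d auxiliary, %d distance-sampled\n",
              nrow(x$counts_us_thermal), nrow(x$counts_us_aux),
              nrow(x$counts_ru)))
  cat(sprintf("  detections: %d thermal, %d auxiliary, %d with distances\n",
              sum(x$counts_us_thermal$count), sum(x$counts_us_aux$count),
              sum(x$counts_ru$count)))
  cat(sprintf("  group sizes recorded: %d; flyover trials: %d of %d detected\n",
              nrow(x$groups), x$trials$detected, x$trials$trials))
  invisible(x)
}
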