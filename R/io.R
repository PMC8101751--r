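#' Write survey tables as delimited text
#'
#' Serializes a survey (grid, covariates, effort, the five observation
#' tables and the scenario that generated them, when present) as UTF-8 CSV
#' files with header rows, one file per table, under `dir`:
#' `grid.csv`, `covariates.csv`, `effort.csv`, `tracks_us.csv`,
#' `tracks_ru.csv`, `counts_us_thermal.csv`, `counts_us_aux.csv`,
#' `counts_ru.csv`, `distances.csv`, `trials.csv`, `groups.csv`, and
#' `scenario.yaml` (structured config). Column names are documented in
#' [read_survey_tables()].
#'
#' @param survey a `survey_data` list.
#' @param grid a `study_grid`.
#' @param cov a `covariate_field`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey_tables <- function(survey, grid, cov, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(as.data.frame(grid), "grid")
  wr(as.data.frame(cov), "covariates")
  for (nm in c("effort", "tracks_us", "tracks_ru", "counts_us_thermal",
               "counts_us_aux", "counts_ru", "distances", "trials",
               "groups")) {
    wr(survey[[nm]], nm)
  }
  if (!is.null(survey$truth$scenario)) {
    sc <- survey$truth$scenario
    yaml::write_yaml(lapply(unclass(sc), function(v) {
      if (is.null(names(v))) v else as.list(v)
    }), file.path(dir, "scenario.yaml"))
  }
  invisible(dir)
}

#' Read survey tables from delimited text
#'
#' Reads the CSV schema written by [write_survey_tables()]. The tables are:
#' `grid.csv` (`cell_id`, `easting`, `northing`, `area`, `saltwater_prop`,
#' `region_*` flags), `covariates.csv` (`cell_id`, `day`, `ice`, `water99`,
#' `dist_land`, `rsf`, `easting_std`, `northing_std`, `dist_land_std`),
#' `tracks_us.csv` (`cell_id`, `day`, `photos`, `photos_with_tracks`),
#' `tracks_ru.csv` (`cell_id`, `day`, `length_km`, `tracks`),
#' `counts_us_thermal.csv` / `counts_us_aux.csv` (`cell_id`, `day`, `count`,
#' `footprint_km2`), `counts_ru.csv` (`cell_id`, `day`, `count`,
#' `length_km`), `distances.csv` (`cell_id`, `day`, `distance_m`),
#' `trials.csv` (`detected`, `trials`), `groups.csv` (`group_id`,
#' `platform`, `size`).
#'
#' @param dir directory containing the tables.
#' @return list with `survey` (a `survey_data`), `grid` (a `study_grid`)
#'   and `cov` (a `covariate_field`).
#' @export
read_survey_tables <- function(dir) {
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) stop("missing survey table: ", f)
    utils::read.csv(f)
  }
  grid <- rd("grid")
  km <- sqrt(grid$area[1])
  attr(grid, "nx") <- length(unique(grid$easting))
  attr(grid, "ny") <- length(unique(grid$northing))
  attr(grid, "cell_km") <- km
  class(grid) <- c("study_grid", "data.frame")
  validate_grid(grid)
  cov <- rd("covariates")
  attr(cov, "S") <- nrow(grid)
  attr(cov, "T_days") <- max(cov$day)
  class(cov) <- c("covariate_field", "data.frame")
  survey <- list(
    tracks_us = rd("tracks_us"), tracks_ru = rd("tracks_ru"),
    counts_us_thermal = rd("counts_us_thermal"),
    counts_us_aux = rd("counts_us_aux"),
    counts_ru = rd("counts_ru"), distances = rd("distances"),
    trials = rd("trials"), groups = rd("groups"))
  eff <- file.path(dir, "effort.csv")
  if (file.exists(eff)) survey$effort <- utils::read.csv(eff)
  class(survey) <- "survey_data"
  list(survey = survey, grid = grid, cov = cov)
}

#' Export grid cells as GeoJSON polygons
#'
#' Writes the square cell outlines with their attributes as a GeoJSON
#' FeatureCollection on the planar (km) coordinate system of the grid.
#'
#' @param grid a `study_grid`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_grid_geojson <- function(grid, file) {
  half <- attr(grid, "cell_km") / 2
  if (is.null(half)) half <- sqrt(grid$area[1]) / 2
  features <- lapply(seq_len(nrow(grid)), function(i) {
    e <- grid$easting[i]; n <- grid$northing[i]
    ring <- list(c(e - half, n - half), c(e + half, n - half),
                 c(e + half, n + half), c(e - half, n + half),
                 c(e - half, n - half))
    list(type = "Feature",
         properties = list(cell_id = grid$cell_id[i],
                           area = grid$area[i],
                           saltwater_prop = grid$saltwater_prop[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
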