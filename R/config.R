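#' Pipeline run configuration
#'
#' Bundles every tunable constant of the analysis pipeline in one validated
#' object. Defaults are the study conditions used throughout: a 100 m/min
#' speed ceiling for plausible cat movement, the 15 m/min + 165--180 degree
#' spike geometry, a 06:00--17:59 local-clock day window, 95/50% kernel
#' isopleths, a 66 m road-sampling disc, a 300 m owner-centred availability
#' buffer, a 10:1 available:used ratio, 85% confidence intervals for
#' AICc-based retention, and a 20% buffer safety margin.
#'
#' @param crs_epsg integer EPSG code of the projected CRS all geometry lives
#'   in (default 32617, UTM zone 17N / WGS84). Only UTM codes are understood
#'   by the built-in projector.
#' @param speed_threshold speed ceiling in m/min; fixes arriving faster are
#'   treated as GPS error.
#' @param spike_speed minimum leg speed (m/min) for the spike test.
#' @param spike_angle_range length-2 numeric, degrees, the turning-angle
#'   window (180 = full reversal) that marks a spike.
#' @param stationary_tol distance in metres under which successive fixes
#'   count as stationary duplicates.
#' @param day_window length-2 character `c("06:00", "17:59")`, inclusive
#'   local-clock bounds of the diurnal period.
#' @param kde_isopleths percent levels for kernel home ranges.
#' @param kde_grid cells per axis of the kernel density grid.
#' @param road_radius radius (m) of the road-density sampling disc.
#' @param owner_buffer_radius radius (m) of the owner-centred RSF boundary.
#' @param avail_ratio available points generated per used point.
#' @param ci_level_glm confidence level for home-range GLM retention.
#' @param ci_level_rsf confidence level for selection coefficients.
#' @param delta_aicc_cut Delta-AICc below which candidate models are kept.
#' @param buffer_margin fractional safety margin added to the buffer
#'   diameter.
#' @param rng_seed integer seed recorded with outputs.
#' @param blocklist list of circular exclusion zones, each
#'   `list(x=, y=, radius=)` in metres; fixes inside any circle are dropped
#'   before all other filters.
#' @return object of class `roam_config` (a validated list).
#' @export
roam_config <- function(crs_epsg = 32617,
                        speed_threshold = 100,
                        spike_speed = 15,
                        spike_angle_range = c(165, 180),
                        stationary_tol = 1e-9,
                        day_window = c("06:00", "17:59"),
                        kde_isopleths = c(95, 50),
                        kde_grid = 200,
                        road_radius = 66,
                        owner_buffer_radius = 300,
                        avail_ratio = 10,
                        ci_level_glm = 0.85,
                        ci_level_rsf = 0.95,
                        delta_aicc_cut = 2.0,
                        buffer_margin = 0.20,
                        rng_seed = 1L,
                        blocklist = list()) {
  stopifnot(
    length(spike_angle_range) == 2L,
    is.numeric(spike_angle_range)
  )
  if (any(c(speed_threshold, spike_speed, stationary_tol, road_radius,
            owner_buffer_radius, kde_grid) <= 0))
    stop("all distances, speeds and grid sizes must be > 0")
  if (ci_level_glm <= 0 || ci_level_glm >= 1 ||
      ci_level_rsf <= 0 || ci_level_rsf >= 1)
    stop("confidence levels must lie strictly between 0 and 1")
  if (avail_ratio < 1) stop("avail_ratio must be >= 1")
  if (spike_angle_range[1] > spike_angle_range[2] ||
      spike_angle_range[1] < 0 || spike_angle_range[2] > 180)
    stop("spike_angle_range must be an ordered pair within [0, 180]")
  if (buffer_margin < 0) stop("buffer_margin must be >= 0")
  for (b in blocklist) {
    if (!all(c("x", "y", "radius") %in% names(b)) || b$radius <= 0)
      stop("each blocklist entry needs x, y and a positive radius")
  }
  structure(
    list(crs_epsg = as.integer(crs_epsg),
         speed_threshold = speed_threshold,
         spike_speed = spike_speed,
         spike_angle_range = spike_angle_range,
         stationary_tol = stationary_tol,
         day_window = day_window,
         kde_isopleths = kde_isopleths,
         kde_grid = as.integer(kde_grid),
         road_radius = road_radius,
         owner_buffer_radius = owner_buffer_radius,
         avail_ratio = as.integer(avail_ratio),
         ci_level_glm = ci_level_glm,
         ci_level_rsf = ci_level_rsf,
         delta_aicc_cut = delta_aicc_cut,
         buffer_margin = buffer_margin,
         rng_seed = as.integer(rng_seed),
         blocklist = blocklist),
    class = "roam_config")
}

#' @export
print.roam_config <- function(x, ...) {
  cat("<roam_config>\n")
  for (nm in setdiff(names(x), "blocklist"))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  cat(sprintf("  %-20s %d zone(s)\n", "blocklist", length(x$blocklist)))
  invisible(x)
}

#' Short reproducibility hash of a configuration
#'
#' @param config a `roam_config`.
#' @return character scalar, a stable hash of every configuration field.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "roam_config"))
  rlang::hash(unclass(config))
}

# land-cover scheme used throughout; order is the code order of rasters
ROAM_CATEGORIES <- c("impervious", "road", "greenspace", "agriculture",
                     "undifferentiated", "water")

# categories excluded from habitat-selection designs
ROAM_EXCLUDED_CATEGORIES <- c("undifferentiated", "water")
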