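# Per-animal predictor construction: road length inside a fixed-radius disc
# centred on the animal's mean coordinates, the major-road presence flag,
# owner-rated personality scoring (neuroticism as the mean of its 13 Likert
# items, with Cronbach's alpha for inter-item reliability), and assembly of
# the modelling table.

#' Total road length inside a sampling disc
#'
#' Sum of the geometric intersection of every road polyline with the CLOSED
#' disc (length lying exactly on the boundary counts). Additive over
#' features and monotone in the radius.
#'
#' @param roads a `roam_roads`.
#' @param center length-2 numeric `(x, y)` in metres.
#' @param radius disc radius in metres (> 0).
#' @return metres of road inside the disc (0 when no roads reach it).
#' @export
road_length_in_circle <- function(roads, center, radius) {
  stopifnot(radius > 0)
  sum(vapply(unclass(roads), function(f)
    polyline_length_in_disc(f$coords, center[1], center[2], radius),
    numeric(1)))
}

#' Road-sampling radius from the median kernel home range
#'
#' Radius of the circle whose area equals the median 95% KDE home-range
#' area: `sqrt(median(area) * 1e4 / pi)`, rounded to the nearest metre.
#'
#' @param areas_ha 95% KDE areas in hectares.
#' @return radius in metres (integer-valued).
#' @export
radius_from_median_kde <- function(areas_ha) {
  stopifnot(length(areas_ha) >= 1)
  med <- stats::median(areas_ha)
  if (med <= 0) stop("median area must be positive")
  round(sqrt(med * 1e4 / pi))
}

#' Major-road presence near a home range
#'
#' 1 when any road classed `"major"` intersects the (closed) MCP polygon --
#' a tangency at a hull vertex counts.
#'
#' @param roads a `roam_roads`.
#' @param mcp_polygon counter-clockwise convex ring (e.g.
#'   `mcp(fixes)$polygons[[1]]`).
#' @return integer 0 or 1.
#' @export
major_road_flag <- function(roads, mcp_polygon) {
  for (f in unclass(roads)) {
    if (is.null(f$class)) stop("road feature without class attribute")
    if (f$class == "major" &&
        polyline_intersects_convex(f$coords, mcp_polygon))
      return(1L)
  }
  0L
}

#' Score neuroticism from a personality survey
#'
#' Likert items are integers 1--7; the raw neuroticism score is the mean of
#' the 13 items mapped to that domain, and the reported score is the
#' z-standardisation of the raw scores across animals. Raw means are always
#' returned so either convention is recoverable.
#'
#' @param survey data.frame: `animal_id` plus one column per item.
#' @param item_map data.frame `(item, domain)` covering every item column;
#'   the neuroticism domain must map exactly 13 items. Which items those
#'   are comes from the survey instrument, so the map is an input, never
#'   hard-coded.
#' @return data.frame `(animal_id, neuroticism_raw, neuroticism)`; the
#'   standardized column is NA (with a warning) when the raw scores have
#'   zero variance.
#' @export
neuroticism_score <- function(survey, item_map) {
  stopifnot(all(c("item", "domain") %in% names(item_map)))
  items <- item_map$item[item_map$domain == "neuroticism"]
  if (length(items) != 13)
    stop("item map must assign exactly 13 items to neuroticism, got ",
         length(items))
  missing <- setdiff(items, names(survey))
  if (length(missing))
    stop("missing neuroticism item(s): ", paste(missing, collapse = ", "))
  ratings <- as.matrix(survey[, items])
  if (anyNA(ratings)) stop("incomplete ratings for neuroticism items")
  if (!all(ratings %in% 1:7)) stop("ratings must be integers 1..7")
  raw <- rowMeans(ratings)
  if (stats::sd(raw) == 0) {
    warning("zero variance in raw scores; standardized score undefined")
    std <- rep(NA_real_, length(raw))
  } else {
    std <- as.numeric(scale(raw))
  }
  data.frame(animal_id = survey$animal_id, neuroticism_raw = raw,
             neuroticism = std, stringsAsFactors = FALSE)
}

#' Cronbach's alpha
#'
#' Inter-item reliability `alpha = k/(k-1) * (1 - sum(item variances) /
#' var(total score))`.
#'
#' @param items numeric matrix, one row per animal, one column per item.
#' @return alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  stopifnot(k >= 2, nrow(items) >= 2)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Assemble the per-animal covariate table
#'
#' Joins home-range responses with intrinsic predictors (sex, age,
#' neuroticism) and extrinsic predictors (road density within
#' `config$road_radius` of the mean coordinates, major-road presence in the
#' 100% MCP, ordinal start date).
#'
#' @param fixes cleaned fixes `(animal_id, t, x, y)`.
#' @param roads a `roam_roads`.
#' @param metadata data.frame `(animal_id, sex, age)`; optional rows may be
#'   missing or NA.
#' @param personality output of [neuroticism_score()], or NULL.
#' @param config a [roam_config()].
#' @return data.frame, one row per animal: `animal_id`, `mean_x`, `mean_y`,
#'   `mcp_area_ha`, `road_density`, `major_road`, `start_ordinal_date`,
#'   `sex`, `age`, `neuroticism`.
#' @export
build_covariates <- function(fixes, roads, metadata = NULL,
                             personality = NULL, config = roam_config()) {
  ids <- unique(fixes$animal_id)
  rows <- lapply(ids, function(id) {
    tr <- fixes[fixes$animal_id == id, , drop = FALSE]
    hr <- mcp(tr, animal_id = id)
    ctr <- c(mean(tr$x), mean(tr$y))
    data.frame(
      animal_id = id, mean_x = ctr[1], mean_y = ctr[2],
      mcp_area_ha = hr$area_ha,
      road_density = road_length_in_circle(roads, ctr, config$road_radius),
      major_road = major_road_flag(roads, hr$polygons[[1]]),
      start_ordinal_date = as.integer(format(min(tr$t), "%j")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sex <- NA_character_
  out$age <- NA_real_
  out$neuroticism <- NA_real_
  if (!is.null(metadata)) {
    m <- match(out$animal_id, metadata$animal_id)
    if ("sex" %in% names(metadata)) out$sex <- metadata$sex[m]
    if ("age" %in% names(metadata)) out$age <- metadata$age[m]
  }
  if (!is.null(personality)) {
    m <- match(out$animal_id, personality$animal_id)
    out$neuroticism <- personality$neuroticism[m]
  }
  out
}
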