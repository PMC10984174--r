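# Readers and writers for the pipeline's external formats: GPS fix tables
# (CSV or GPX), categorical land cover (ESRI ASCII grid or GeoJSON polygons,
# normalised to the six-way scheme through a user-supplied mapping table),
# road networks (GeoJSON lines with a major/minor class), home-range
# polygons (GeoJSON) and CSV result tables with a reproducibility sidecar.

.parse_timestamps <- function(ts) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS")
  out <- tryCatch(as.POSIXct(ts, tz = "", tryFormats = fmts),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  # vector parse failed: recover per element so bad rows can be named
  vapply(as.character(ts), function(s)
    tryCatch(as.numeric(as.POSIXct(s, tz = "", tryFormats = fmts)),
             error = function(e) NA_real_),
    numeric(1), USE.NAMES = FALSE) |>
    as.POSIXct(origin = "1970-01-01", tz = "")
}

#' Read GPS fixes from CSV or GPX
#'
#' CSV input needs columns `(animal_id, timestamp, lon, lat)` or
#' `(animal_id, timestamp, x, y)`; lon/lat are projected once into the
#' configured UTM CRS. Output is sorted by `(animal_id, t)`; exact duplicate
#' records are dropped with a message, while two different positions at the
#' same `(animal_id, t)` raise an error.
#'
#' @param path CSV or GPX file.
#' @param config a [roam_config()]; supplies the target CRS.
#' @return data.frame `(animal_id, t, x, y)`, plus `lon`/`lat` columns when
#'   the source was geographic.
#' @export
read_fixes <- function(path, config = roam_config()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gpx") {
    df <- .read_gpx(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  has_xy <- all(c("x", "y") %in% names(df))
  has_ll <- all(c("lon", "lat") %in% names(df))
  if (!all(c("animal_id", "timestamp") %in% names(df)) || !(has_xy || has_ll))
    stop("fix table needs (animal_id, timestamp) plus lon/lat or x/y columns")
  t <- suppressWarnings(.parse_timestamps(df$timestamp))
  if (anyNA(t)) {
    bad <- which(is.na(t))
    stop("unparseable timestamp in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (has_ll && !has_xy) {
    pr <- lonlat_to_utm(df$lon, df$lat, config$crs_epsg)
    df$x <- pr$x; df$y <- pr$y
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates in fix table")
  out <- data.frame(animal_id = as.character(df$animal_id), t = t,
                    x = df$x, y = df$y, stringsAsFactors = FALSE)
  if (has_ll) { out$lon <- df$lon; out$lat <- df$lat }
  out <- out[order(out$animal_id, out$t), , drop = FALSE]
  key <- paste(out$animal_id, format(out$t, "%Y-%m-%d %H:%M:%OS3"),
               signif(out$x, 12), signif(out$y, 12))
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate", if (sum(dup) > 1) "s", " dropped")
    out <- out[!dup, , drop = FALSE]
  }
  tkey <- paste(out$animal_id, format(out$t, "%Y-%m-%d %H:%M:%OS3"))
  conflict <- duplicated(tkey)
  if (any(conflict)) {
    i <- which(conflict)[1]
    stop("conflicting positions at identical (animal_id, t): ",
         out$animal_id[i], " @ ", format(out$t[i]))
  }
  rownames(out) <- NULL
  out
}

.read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  rows <- list()
  for (trk in trks) {
    id <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(id) || id == "") id <- "track"
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = id,
      timestamp = xml2::xml_text(xml2::xml_find_first(pts, "./time")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write fixes back to CSV
#' @param fixes fix data.frame.
#' @param path output CSV path.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$t, "%Y-%m-%d %H:%M:%S")
  out$t <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- land cover -----------------------------------------------------------

#' Construct a categorical raster landscape
#'
#' @param grid integer matrix of category codes, `grid[row, col]` with row 1
#'   the NORTHern edge (ASCII-grid convention).
#' @param xmin,ymin lower-left corner in metres.
#' @param cell cell size in metres.
#' @param categories character vector: `categories[code]` names code `code`.
#' @return object of class `roam_landscape` (raster flavour).
#' @export
landscape_raster <- function(grid, xmin, ymin, cell, categories) {
  stopifnot(is.matrix(grid), cell > 0, length(categories) >= max(grid))
  structure(list(type = "raster", grid = grid, xmin = xmin, ymin = ymin,
                 cell = cell, categories = categories),
            class = "roam_landscape")
}

#' @export
print.roam_landscape <- function(x, ...) {
  if (x$type == "raster") {
    cat(sprintf("<roam_landscape raster %d x %d cells, %g m>\n",
                nrow(x$grid), ncol(x$grid), x$cell))
    print(round(prop.table(table(x$categories[x$grid])), 3))
  } else {
    cat(sprintf("<roam_landscape polygons, %d features>\n", length(x$features)))
  }
  invisible(x)
}

#' Landscape extent
#' @param landscape a `roam_landscape`.
#' @return named vector `xmin, xmax, ymin, ymax`.
#' @export
landscape_extent <- function(landscape) {
  if (landscape$type == "raster") {
    c(xmin = landscape$xmin,
      xmax = landscape$xmin + ncol(landscape$grid) * landscape$cell,
      ymin = landscape$ymin,
      ymax = landscape$ymin + nrow(landscape$grid) * landscape$cell)
  } else {
    xs <- unlist(lapply(landscape$features, function(f) f$ring[, 1]))
    ys <- unlist(lapply(landscape$features, function(f) f$ring[, 2]))
    c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
  }
}

#' Land-cover category at point locations
#'
#' Raster layers use the cell containing the point (cell edges belong to the
#' cell to their north-east, the last row/column closed); polygon layers use
#' point-in-polygon with boundary points assigned to the first containing
#' feature in file order.
#'
#' @param landscape a `roam_landscape`.
#' @param x,y point coordinates (vectorised).
#' @return character vector of category names; points outside the extent
#'   raise an error.
#' @export
landscape_category <- function(landscape, x, y) {
  ext <- landscape_extent(landscape)
  if (any(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]))
    stop("point(s) outside landscape extent")
  if (landscape$type == "raster") {
    nx <- ncol(landscape$grid); ny <- nrow(landscape$grid)
    ix <- pmin(floor((x - landscape$xmin) / landscape$cell) + 1L, nx)
    iy <- pmin(floor((y - landscape$ymin) / landscape$cell) + 1L, ny)
    row <- ny - iy + 1L   # row 1 is the northern edge
    landscape$categories[landscape$grid[cbind(row, ix)]]
  } else {
    out <- rep(NA_character_, length(x))
    for (f in landscape$features) {
      todo <- is.na(out)
      if (!any(todo)) break
      hit <- point_in_polygon(x[todo], y[todo], f$ring)
      out[todo][hit] <- f$category
    }
    if (anyNA(out)) stop("point(s) not covered by any land-cover polygon")
    out
  }
}

#' Read land cover from ESRI ASCII grid or GeoJSON polygons
#'
#' A mapping table (data.frame `code`, `category`) normalises source codes
#' to the six-way scheme (impervious, road, greenspace, agriculture,
#' undifferentiated, water). Codes present in the data but missing from the
#' mapping raise an error that lists them.
#'
#' @param path `.asc` raster or `.geojson`/`.json` polygons.
#' @param mapping data.frame with columns `code` and `category`; for GeoJSON
#'   the `code` column matches the features' `category` property. `NULL`
#'   accepts GeoJSON properties that are already canonical names.
#' @return a `roam_landscape`.
#' @export
read_landscape <- function(path, mapping = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    if (is.null(mapping)) stop("raster land cover requires a mapping table")
    .read_landscape_asc(path, mapping)
  } else {
    .read_landscape_geojson(path, mapping)
  }
}

.check_mapping <- function(codes, mapping) {
  unmapped <- setdiff(codes, mapping$code)
  if (length(unmapped))
    stop("unmapped land-cover code(s): ", paste(unmapped, collapse = ", "))
  bad <- setdiff(mapping$category, ROAM_CATEGORIES)
  if (length(bad))
    stop("mapping target(s) outside the category scheme: ",
         paste(bad, collapse = ", "))
}

.read_landscape_asc <- function(path, mapping) {
  hdr <- utils::read.table(path, nrows = 6, stringsAsFactors = FALSE)
  h <- stats::setNames(as.numeric(hdr[[2]]), tolower(hdr[[1]]))
  vals <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(vals) <- NULL
  stopifnot(nrow(vals) == h["nrows"], ncol(vals) == h["ncols"])
  .check_mapping(sort(unique(as.vector(vals))), mapping)
  # recode to 1..k positions in ROAM_CATEGORIES
  cat_of_code <- stats::setNames(mapping$category, mapping$code)
  grid <- matrix(match(cat_of_code[as.character(vals)], ROAM_CATEGORIES),
                 nrow = nrow(vals))
  landscape_raster(grid, unname(h["xllcorner"]), unname(h["yllcorner"]),
                   unname(h["cellsize"]), ROAM_CATEGORIES)
}

.read_landscape_geojson <- function(path, mapping) {
  gj <- jsonlite::read_json(path)
  feats <- list()
  raw_codes <- character()
  for (f in gj$features) {
    code <- as.character(f$properties$category)
    raw_codes <- union(raw_codes, code)
    geom <- f$geometry
    rings <- if (geom$type == "Polygon") list(geom$coordinates) else
      if (geom$type == "MultiPolygon") geom$coordinates else
        stop("unsupported geometry type: ", geom$type)
    for (poly in rings) {
      ring <- do.call(rbind, lapply(poly[[1]], function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      # drop the GeoJSON closing vertex
      if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), ]
      feats[[length(feats) + 1L]] <- list(ring = ring, category = code)
    }
  }
  if (!is.null(mapping)) {
    .check_mapping(raw_codes, mapping)
    cat_of_code <- stats::setNames(mapping$category, mapping$code)
    for (i in seq_along(feats))
      feats[[i]]$category <- unname(cat_of_code[feats[[i]]$category])
  } else {
    bad <- setdiff(raw_codes, ROAM_CATEGORIES)
    if (length(bad))
      stop("unmapped land-cover code(s): ", paste(bad, collapse = ", "))
  }
  structure(list(type = "polygon", features = feats),
            class = "roam_landscape")
}

#' Write a raster landscape as ESRI ASCII grid
#' @param landscape raster `roam_landscape`.
#' @param path output `.asc` path.
#' @return the path, invisibly. Codes written are positions in
#'   `landscape$categories`; pair with [write_landscape_mapping()].
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(landscape$type == "raster")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(landscape$grid)),
    paste("nrows", nrow(landscape$grid)),
    paste("xllcorner", format(landscape$xmin, scientific = FALSE)),
    paste("yllcorner", format(landscape$ymin, scientific = FALSE)),
    paste("cellsize", format(landscape$cell, scientific = FALSE)),
    "NODATA_value -9999"), con)
  utils::write.table(landscape$grid, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write the code-to-category mapping for a raster landscape
#' @param landscape raster `roam_landscape`.
#' @param path output CSV path.
#' @export
write_landscape_mapping <- function(landscape, path) {
  utils::write.csv(data.frame(code = seq_along(landscape$categories),
                              category = landscape$categories),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- roads ----------------------------------------------------------------

#' Read a road network from GeoJSON lines
#'
#' Every feature must carry a `class` property equal to `"major"` or
#' `"minor"`.
#'
#' @param path GeoJSON file of LineString / MultiLineString features.
#' @return object of class `roam_roads`: list of
#'   `list(coords = matrix, class = chr)`.
#' @export
read_roads <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- list()
  for (f in gj$features) {
    cls <- f$properties$class
    if (is.null(cls) || !cls %in% c("major", "minor"))
      stop("road feature without a major/minor class attribute")
    geom <- f$geometry
    lines <- if (geom$type == "LineString") list(geom$coordinates) else
      if (geom$type == "MultiLineString") geom$coordinates else
        stop("unsupported road geometry: ", geom$type)
    for (ln in lines) {
      coords <- do.call(rbind, lapply(ln, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      feats[[length(feats) + 1L]] <- list(coords = coords, class = cls)
    }
  }
  structure(feats, class = "roam_roads")
}

#' Write a road network to GeoJSON
#' @param roads a `roam_roads`.
#' @param path output path.
#' @export
write_roads <- function(roads, path) {
  feats <- lapply(unclass(roads), function(f) {
    list(type = "Feature",
         properties = list(class = f$class),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(f$coords)),
                                              function(i) as.numeric(f$coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- home-range polygons --------------------------------------------------

#' Write home-range estimates as GeoJSON polygons
#' @param estimates list of `homerange_estimate` objects (or a single one).
#' @param path output path.
#' @export
write_homeranges <- function(estimates, path) {
  if (inherits(estimates, "homerange_estimate")) estimates <- list(estimates)
  feats <- lapply(estimates, function(e) {
    polys <- lapply(e$polygons, function(ring) {
      ring_closed <- rbind(ring, ring[1, , drop = FALSE])
      list(lapply(seq_len(nrow(ring_closed)), function(i)
        as.numeric(ring_closed[i, ])))
    })
    list(type = "Feature",
         properties = list(animal_id = e$animal_id, method = e$method,
                           level = e$level, period = e$period,
                           area_ha = e$area_ha, n_fixes = e$n_fixes),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read home-range polygons written by [write_homeranges()]
#' @param path GeoJSON path.
#' @return list of `homerange_estimate`-like lists.
#' @export
read_homeranges <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    polys <- lapply(f$geometry$coordinates, function(poly) {
      ring <- do.call(rbind, lapply(poly[[1]], function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      ring[-nrow(ring), , drop = FALSE]
    })
    structure(list(animal_id = f$properties$animal_id,
                   method = f$properties$method,
                   level = f$properties$level,
                   period = f$properties$period,
                   area_ha = f$properties$area_ha,
                   n_fixes = f$properties$n_fixes,
                   polygons = polys),
              class = "homerange_estimate")
  })
}

# ---- result tables --------------------------------------------------------

#' Write a result table with a reproducibility sidecar
#'
#' Writes `path` as CSV and `path.meta.json` holding the configuration hash
#' and RNG seed, so any output can be traced to the run that made it.
#'
#' @param df data.frame to write.
#' @param path CSV path.
#' @param config the run's [roam_config()].
#' @export
write_results <- function(df, path, config = roam_config()) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(config_hash = config_hash(config),
                            rng_seed = config$rng_seed,
                            written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
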