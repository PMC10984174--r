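# Home-range estimation and the statistics derived from it: 100% minimum
# convex polygons, kernel-density isopleths via grid volume contours, the
# day/night split, the sample-size asymptote diagnostic, equivalent-circle
# buffer geometry, and the paired/spread tests used to compare range sizes.

new_homerange_estimate <- function(animal_id, method, level, polygons,
                                   area_ha, n_fixes, bandwidth = NA_real_,
                                   period = "all") {
  structure(list(animal_id = animal_id, method = method, level = level,
                 polygons = polygons, area_ha = area_ha, n_fixes = n_fixes,
                 bandwidth = bandwidth, period = period),
            class = "homerange_estimate")
}

#' @export
print.homerange_estimate <- function(x, ...) {
  cat(sprintf("<homerange %s %g%% %s/%s: %.4f ha, n = %d>\n",
              x$method, x$level, x$animal_id, x$period, x$area_ha, x$n_fixes))
  invisible(x)
}

#' Minimum convex polygon home range
#'
#' Convex hull of the fixes; for `level < 100` the `(100-level)%` of fixes
#' farthest from the centroid (arithmetic mean location) are dropped first.
#' Area by the planar shoelace formula, reported in hectares.
#'
#' @param fixes data.frame with `x`, `y` (one animal).
#' @param level percent of fixes retained (default 100).
#' @param animal_id,period labels carried into the estimate.
#' @return a `homerange_estimate` with one polygon.
#' @export
mcp <- function(fixes, level = 100, animal_id = "animal", period = "all") {
  x <- fixes$x; y <- fixes$y
  if (level < 100) {
    d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    keep <- order(d)[seq_len(max(3L, floor(length(x) * level / 100)))]
    x <- x[keep]; y <- y[keep]
  }
  if (length(unique(paste(x, y))) < 3) stop("degenerate hull")
  hull <- convex_hull(x, y)
  area <- polygon_area(hull)
  if (area <= 0) stop("degenerate hull")
  new_homerange_estimate(animal_id, "MCP", level, list(hull),
                         area / 1e4, nrow(fixes), period = period)
}

#' Reference bandwidth for kernel home ranges
#'
#' The ad hoc (href) rule: `sigma * n^(-1/6)` with
#' `sigma = sqrt((var(x) + var(y)) / 2)`.
#'
#' @param fixes data.frame with `x`, `y`.
#' @return bandwidth in metres.
#' @export
href_bandwidth <- function(fixes) {
  sqrt((stats::var(fixes$x) + stats::var(fixes$y)) / 2) *
    nrow(fixes)^(-1 / 6)
}

#' Kernel-density isopleth home range
#'
#' Bivariate Gaussian kernel density evaluated on a regular grid covering
#' the fixes' bounding box padded by three bandwidths. The isopleth is the
#' smallest set of grid cells whose summed probability mass reaches
#' `level`% (the classic utilization-distribution volume contour); its area
#' is cell count times cell area. Output polygons are density contour rings
#' at the isopleth's density cutoff.
#'
#' @param fixes data.frame with `x`, `y` (>= 5 rows).
#' @param level isopleth percent (e.g. 95 or 50).
#' @param bandwidth kernel sd in metres; default [href_bandwidth()].
#' @param grid cells per axis.
#' @param animal_id,period labels carried into the estimate.
#' @return a `homerange_estimate` (possibly several polygons).
#' @export
kde_isopleth <- function(fixes, level = 95, bandwidth = NULL, grid = 200,
                         animal_id = "animal", period = "all") {
  stopifnot(nrow(fixes) >= 5)
  x <- fixes$x; y <- fixes$y
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both axes")
  h <- if (is.null(bandwidth)) href_bandwidth(fixes) else bandwidth
  if (h <= 0) stop("bandwidth must be positive")
  gx <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = grid)
  gy <- seq(min(y) - 3 * h, max(y) + 3 * h, length.out = grid)
  dxm <- stats::dnorm(outer(gx, x, "-"), sd = h)
  dym <- stats::dnorm(outer(gy, y, "-"), sd = h)
  dens <- dxm %*% t(dym) / length(x)          # dens[i, j] at (gx[i], gy[j])
  cellx <- gx[2] - gx[1]; celly <- gy[2] - gy[1]
  mass <- dens * cellx * celly
  mass <- mass / sum(mass)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  ncell <- which(cum >= level / 100)[1]
  if (is.na(ncell)) ncell <- length(ord)
  cutoff <- dens[ord[ncell]]
  area <- ncell * cellx * celly
  rings <- lapply(grDevices::contourLines(gx, gy, dens, levels = cutoff),
                  function(cl) cbind(x = cl$x, y = cl$y))
  new_homerange_estimate(animal_id, "KDE", level, rings, area / 1e4,
                         nrow(fixes), bandwidth = h, period = period)
}

#' Split fixes into diurnal and nocturnal subsets
#'
#' Day is the closed clock window `day_window` (default 06:00--17:59 local
#' time, minute resolution); everything else is night. The two subsets
#' partition the input.
#'
#' @param fixes data.frame with POSIXct `t`.
#' @param day_window length-2 `"HH:MM"` character.
#' @return list with `day` and `night` data.frames.
#' @export
split_day_night <- function(fixes, day_window = c("06:00", "17:59")) {
  mins <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }
  lo <- mins(day_window[1]); hi <- mins(day_window[2])
  mod <- as.integer(format(fixes$t, "%H")) * 60 +
    as.integer(format(fixes$t, "%M"))
  is_day <- mod >= lo & mod <= hi
  list(day = fixes[is_day, , drop = FALSE],
       night = fixes[!is_day, , drop = FALSE])
}

#' Home-range asymptote diagnostic
#'
#' MCP area as fixes accumulate chronologically. The plateau flag replaces
#' visual inspection: TRUE when the area grows by less than
#' `growth_tol` (default 5%) over the final `window` fraction (default 20%)
#' of the curve.
#'
#' @param fixes data.frame `(t, x, y)`, chronological.
#' @param step fix-count increment between curve points.
#' @param window final fraction of the curve examined.
#' @param growth_tol relative growth below which the curve counts as flat.
#' @return list `curve` (data.frame `n`, `area_ha`) and `plateau` (logical).
#' @export
asymptote_curve <- function(fixes, step = 10, window = 0.20,
                            growth_tol = 0.05) {
  n <- nrow(fixes)
  stopifnot(n >= 10)
  counts <- unique(c(seq(3, n, by = step), n))
  area <- vapply(counts, function(m) {
    sub <- fixes[seq_len(m), , drop = FALSE]
    if (length(unique(paste(sub$x, sub$y))) < 3) return(0)
    a <- tryCatch(mcp(sub)$area_ha, error = function(e) 0)
    a
  }, numeric(1))
  curve <- data.frame(n = counts, area_ha = area)
  a_end <- area[length(area)]
  n_start <- counts[length(counts)] * (1 - window)
  i80 <- max(which(counts <= n_start))
  a80 <- area[i80]
  plateau <- a80 > 0 && (a_end - a80) / a80 < growth_tol
  list(curve = curve, plateau = plateau)
}

#' Equivalent-circle diameter of a home-range area
#'
#' The diameter of the circle with the same area:
#' `d = 2 * sqrt(area_ha * 1e4 / pi)`. Reported values are rounded to the
#' nearest 10 m; the raw value is returned alongside.
#'
#' @param area_ha area in hectares (> 0).
#' @return list `diameter_m` (rounded to 10 m) and `raw_m`.
#' @export
equivalent_circle_diameter <- function(area_ha) {
  if (area_ha <= 0) stop("area must be positive")
  d <- 2 * sqrt(area_ha * 1e4 / pi)
  list(diameter_m = round(d / 10) * 10, raw_m = d)
}

#' Buffer distance from a home-range area
#'
#' Equivalent-circle diameter inflated by a fractional safety `margin`,
#' rounded to the nearest 10 m.
#'
#' @param area_ha area in hectares (> 0).
#' @param margin fractional safety margin (>= 0), default 20%.
#' @return list `buffer_m` (rounded to 10 m) and `raw_m`.
#' @export
buffer_distance <- function(area_ha, margin = 0.20) {
  if (margin < 0) stop("margin must be >= 0")
  d <- equivalent_circle_diameter(area_ha)$raw_m * (1 + margin)
  list(buffer_m = round(d / 10) * 10, raw_m = d)
}

#' Wilcoxon signed-rank test for paired home-range areas
#'
#' W is the sum of positive-difference ranks; zero differences are dropped
#' and tied absolute differences get average ranks. For `n <= exact_max`
#' the two-sided p is exact, from the null distribution of W over all sign
#' assignments (computed by convolution over the tied-rank generating
#' function); above that a normal approximation with continuity and tie
#' correction is used.
#'
#' @param a,b paired measurements (e.g. day and night areas per animal).
#' @param exact_max largest n for which the exact distribution is used.
#' @return list `statistic` (W), `p.value`, `n_used`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 12) {
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all differences are zero")
    return(list(statistic = 0, p.value = 1, n_used = 0L, exact = TRUE))
  }
  n <- length(nz)
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  if (n <= exact_max) {
    # null distribution of 2W (integer under average ranks) by convolution
    dr <- as.integer(round(2 * r))
    probs <- c(1)
    for (k in dr) {
      shifted <- c(rep(0, k), probs)
      probs <- (c(probs, rep(0, k)) + shifted) / 2
    }
    w2 <- round(2 * w)
    p_lo <- sum(probs[seq_len(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):length(probs)])
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = w, p.value = p, n_used = n, exact = TRUE)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(w - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    list(statistic = w, p.value = p, n_used = n, exact = FALSE)
  }
}

#' Brown-Forsythe test of equal spread
#'
#' One-way ANOVA F on absolute deviations from the group medians; location
#' shifts between groups do not affect it.
#'
#' @param a,b numeric vectors (the two groups).
#' @return list `statistic` (F), `p.value`, `df1`, `df2`.
#' @export
brown_forsythe <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  z <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  fit <- stats::anova(stats::lm(z ~ g))
  list(statistic = fit$`F value`[1], p.value = fit$`Pr(>F)`[1],
       df1 = fit$Df[1], df2 = fit$Df[2])
}
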