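# Ground-truth simulator. A scenario fixes the landscape composition, the
# movement process (a home-tethered, habitat-weighted step-selection walk),
# the irregular fix schedule, GPS noise, and artifact injection rates, so
# every downstream stage can be checked by parameter recovery.

#' Simulation scenario
#'
#' Defaults describe an urban owned-cat setting: a clustered four-category
#' landscape dominated by impervious surfaces (66%) and roads (26%) with
#' scarce greenspace (6%) and agriculture (2%); fixes every 2--60 min;
#' isotropic GPS error of 4.8 m sd (open-sky collar accuracy); and movement
#' scaled so simulated 100% MCP home ranges land in the observed
#' 0.3--40 ha range.
#'
#' @param n_animals number of animals.
#' @param home_xy matrix (n_animals x 2) of owner-home coordinates; default
#'   spreads homes over the landscape interior.
#' @param landscape_prop named target proportions over categories.
#' @param selection_weights named positive weights, the true point-level
#'   selection strengths; ratios of log weights are the recoverable
#'   contrasts.
#' @param tether_strength per-step fraction of the distance home that is
#'   deterministically closed (0 < tau <= 1).
#' @param step_scale mean exponential step length, metres.
#' @param fix_interval_range minutes, uniform draw bounds.
#' @param gps_sigma GPS error sd per axis, metres.
#' @param outlier_rate,spike_rate,stationary_run_rate artifact injection
#'   probabilities per fix.
#' @param duration_days tracking duration.
#' @param start_spread_days enrolment window: per-animal tracking start
#'   dates are drawn uniformly over this many days (the study season).
#' @param n_candidates candidate displacements per step of the
#'   step-selection kernel.
#' @param turn_sd sd (degrees) of the turning-angle proposal around the
#'   previous heading.
#' @param extent landscape side length, metres.
#' @param cell landscape cell size, metres.
#' @param patch_cells expected land-cover patch size (cells) used by
#'   [generate_landscape()].
#' @param rng_seed integer seed.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_animals = 6,
                         home_xy = NULL,
                         landscape_prop = c(impervious = 0.66, road = 0.26,
                                            greenspace = 0.06,
                                            agriculture = 0.02),
                         selection_weights = c(impervious = 1, road = 1,
                                               greenspace = 1,
                                               agriculture = 1),
                         tether_strength = 0.05,
                         step_scale = 12,
                         fix_interval_range = c(2, 60),
                         gps_sigma = 4.8,
                         outlier_rate = 0,
                         spike_rate = 0,
                         stationary_run_rate = 0,
                         duration_days = 20,
                         start_spread_days = 120,
                         n_candidates = 20,
                         turn_sd = 60,
                         extent = 1000,
                         cell = 5,
                         patch_cells = 400,
                         rng_seed = 1L) {
  if (abs(sum(landscape_prop) - 1) > 1e-9)
    stop("landscape proportions must sum to 1")
  if (any(selection_weights < 0)) stop("selection weights must be >= 0")
  if (tether_strength <= 0 || tether_strength > 1)
    stop("tether_strength must be in (0, 1]")
  rates <- c(outlier_rate, spike_rate, stationary_run_rate)
  if (any(rates < 0 | rates > 1)) stop("artifact rates must be in [0, 1]")
  if (is.null(home_xy)) {
    ang <- 2 * pi * (seq_len(n_animals) - 1) / max(n_animals, 1)
    home_xy <- cbind(extent / 2 + extent / 6 * cos(ang),
                     extent / 2 + extent / 6 * sin(ang))
  }
  structure(list(n_animals = n_animals, home_xy = home_xy,
                 landscape_prop = landscape_prop,
                 selection_weights = selection_weights,
                 tether_strength = tether_strength, step_scale = step_scale,
                 fix_interval_range = fix_interval_range,
                 gps_sigma = gps_sigma, outlier_rate = outlier_rate,
                 spike_rate = spike_rate,
                 stationary_run_rate = stationary_run_rate,
                 duration_days = duration_days,
                 start_spread_days = start_spread_days,
                 n_candidates = n_candidates,
                 turn_sd = turn_sd, extent = extent, cell = cell,
                 patch_cells = patch_cells,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_scenario")
}

#' Generate a clustered categorical landscape
#'
#' Quota-constrained multi-seed region growing: each category claims a cell
#' budget matching its target proportion and grows contiguous patches from
#' random seeds until all budgets are spent, so realized proportions match
#' the targets to rounding while cover stays spatially clustered (as urban
#' land-cover patches are), not i.i.d. cell noise.
#'
#' @param prop named target proportions (sum to 1).
#' @param extent landscape side length, metres (square).
#' @param cell cell size, metres.
#' @param seed integer RNG seed; same seed, same landscape.
#' @param patch_cells expected patch size used to pick the number of seeds.
#' @return a raster `roam_landscape` with categories `names(prop)`.
#' @export
generate_landscape <- function(prop, extent = 1000, cell = 5, seed = 1,
                               patch_cells = 400) {
  if (abs(sum(prop) - 1) > 1e-9) stop("proportions must sum to 1")
  nx <- as.integer(extent / cell); ny <- nx
  if (nx < 50) stop("extent/cell must give at least 50 x 50 cells")
  set.seed(seed)
  ncat <- length(prop)
  ncell <- nx * ny
  quota <- floor(prop * ncell)
  rem <- ncell - sum(quota)
  if (rem > 0) {
    top <- order(prop * ncell - quota, decreasing = TRUE)[seq_len(rem)]
    quota[top] <- quota[top] + 1L
  }
  cat_of <- integer(ncell)                 # 0 = unassigned
  frontier <- vector("list", ncat)
  remaining <- quota
  nb_off <- c(-1L, 1L, -nx, nx)

  unassigned_neighbours <- function(idx) {
    out <- integer(0)
    cx <- ((idx - 1L) %% nx) + 1L
    for (o in nb_off) {
      j <- idx + o
      if (o == -1L && cx == 1L) next
      if (o == 1L && cx == nx) next
      if (j < 1L || j > ncell) next
      if (cat_of[j] == 0L) out <- c(out, j)
    }
    out
  }
  seed_cat <- function(k) {
    free <- which(cat_of == 0L)
    s <- free[sample.int(length(free), 1L)]
    cat_of[s] <<- k
    remaining[k] <<- remaining[k] - 1L
    frontier[[k]] <<- s
  }
  n_seeds <- pmax(1L, round(quota / patch_cells))
  for (k in seq_len(ncat)) {
    for (s in seq_len(n_seeds[k])) if (remaining[k] > 0L) seed_cat(k)
  }
  while (any(remaining > 0L)) {
    act <- which(remaining > 0L)
    k <- if (length(act) == 1L) act else
      sample(act, 1L, prob = remaining[act])
    grown <- FALSE
    while (length(frontier[[k]]) > 0L && !grown) {
      fi <- sample.int(length(frontier[[k]]), 1L)
      cellidx <- frontier[[k]][fi]
      nb <- unassigned_neighbours(cellidx)
      if (!length(nb)) {
        frontier[[k]] <- frontier[[k]][-fi]
      } else {
        pick <- nb[sample.int(length(nb), 1L)]
        cat_of[pick] <- k
        remaining[k] <- remaining[k] - 1L
        frontier[[k]] <- c(frontier[[k]], pick)
        grown <- TRUE
      }
    }
    if (!grown) seed_cat(k)                # patch walled in: reseed
  }
  # cell index runs west->east then south->north; grid row 1 is north
  grid <- matrix(0L, nrow = ny, ncol = nx)
  for (iy in seq_len(ny))
    grid[ny - iy + 1L, ] <- cat_of[((iy - 1L) * nx + 1L):(iy * nx)]
  landscape_raster(grid, 0, 0, cell, names(prop))
}

#' Simulate one animal's true trajectory
#'
#' Discrete-time step-selection walk. Each step proposes `n_candidates`
#' displacements (exponential lengths of mean `step_scale`, headings normal
#' around the previous heading) on top of a deterministic pull of
#' `tether_strength` of the way home, then picks a candidate with
#' probability proportional to `selection_weights` of the land cover at the
#' candidate location. Fix times are cumulative uniform draws from
#' `fix_interval_range`. True between-fix speed stays below 100 m/min by
#' construction (displacements are capped at 95 m per minute of the step's
#' interval). Candidates beyond the landscape edge are reflected (counted
#' in `n_reflected`).
#'
#' @param scenario a [sim_scenario()].
#' @param landscape a `roam_landscape` covering the scenario extent.
#' @param animal animal index (picks the home and the id label).
#' @param t0 POSIXct start time.
#' @param record_candidates also record, per step, the land-cover category
#'   of the chosen candidate and the category counts of the whole candidate
#'   pool. Under uniform selection weights the choice is a uniform draw
#'   from the pool, which gives a valid selection-neutrality check (usage
#'   vs home-range-wide availability does NOT, because a home-tethered walk
#'   over-samples cover near home).
#' @return data.frame `(animal_id, t, x, y)` of TRUE positions, with
#'   attribute `n_reflected`; with `record_candidates`, also attributes
#'   `chosen_cat` (character per step) and `pool_counts` (steps x category
#'   matrix).
#' @export
simulate_trajectory <- function(scenario, landscape, animal = 1,
                                t0 = as.POSIXct("2021-06-01 06:00:00",
                                                tz = ""),
                                record_candidates = FALSE) {
  ext <- landscape_extent(landscape)
  home <- scenario$home_xy[animal, ]
  if (home[1] < ext["xmin"] || home[1] > ext["xmax"] ||
      home[2] < ext["ymin"] || home[2] > ext["ymax"])
    stop("home outside landscape extent")
  w <- scenario$selection_weights
  K <- scenario$n_candidates
  tau <- scenario$tether_strength
  total_min <- scenario$duration_days * 24 * 60
  tmins <- c(0, cumsum(stats::runif(ceiling(total_min / mean(scenario$fix_interval_range)) * 2,
                                    scenario$fix_interval_range[1],
                                    scenario$fix_interval_range[2])))
  tmins <- tmins[tmins <= total_min]
  n <- length(tmins)
  xs <- ys <- numeric(n)
  xs[1] <- home[1]; ys[1] <- home[2]
  heading <- stats::runif(1, 0, 2 * pi)
  n_reflected <- 0L
  cat_names <- if (landscape$type == "raster") landscape$categories else
    unique(vapply(landscape$features, `[[`, character(1), "category"))
  if (record_candidates) {
    chosen_cat <- character(n - 1L)
    pool_counts <- matrix(0L, n - 1L, length(cat_names),
                          dimnames = list(NULL, cat_names))
  }
  reflect <- function(v, lo, hi) {
    # reflect into [lo, hi]
    while (v < lo || v > hi) {
      if (v < lo) v <- 2 * lo - v else v <- 2 * hi - v
    }
    v
  }
  for (i in 2:n) {
    dt <- tmins[i] - tmins[i - 1]
    cap <- 95 * dt
    base_x <- xs[i - 1] + tau * (home[1] - xs[i - 1])
    base_y <- ys[i - 1] + tau * (home[2] - ys[i - 1])
    len <- stats::rexp(K, rate = 1 / scenario$step_scale)
    ang <- heading + stats::rnorm(K, 0, scenario$turn_sd * pi / 180)
    cx <- base_x + len * cos(ang)
    cy <- base_y + len * sin(ang)
    # cap total displacement well under the speed ceiling
    ddx <- cx - xs[i - 1]; ddy <- cy - ys[i - 1]
    dd <- sqrt(ddx^2 + ddy^2)
    f <- pmin(1, cap / pmax(dd, 1e-12))
    cx <- xs[i - 1] + ddx * f
    cy <- ys[i - 1] + ddy * f
    refl <- cx < ext["xmin"] | cx > ext["xmax"] |
      cy < ext["ymin"] | cy > ext["ymax"]
    if (any(refl)) {
      n_reflected <- n_reflected + sum(refl)
      cx[refl] <- vapply(cx[refl], reflect, numeric(1),
                         ext["xmin"], ext["xmax"])
      cy[refl] <- vapply(cy[refl], reflect, numeric(1),
                         ext["ymin"], ext["ymax"])
    }
    cats <- landscape_category(landscape, cx, cy)
    wc <- w[cats]
    wc[is.na(wc)] <- 0
    pick <- if (sum(wc) == 0) which.min(abs(len)) else
      sample.int(K, 1L, prob = wc)
    if (record_candidates) {
      chosen_cat[i - 1L] <- cats[pick]
      tb <- table(factor(cats, levels = cat_names))
      pool_counts[i - 1L, ] <- as.integer(tb)
    }
    xs[i] <- cx[pick]; ys[i] <- cy[pick]
    if (xs[i] != xs[i - 1] || ys[i] != ys[i - 1])
      heading <- atan2(ys[i] - ys[i - 1], xs[i] - xs[i - 1])
  }
  out <- data.frame(animal_id = paste0("cat", animal),
                    t = t0 + tmins * 60, x = xs, y = ys,
                    stringsAsFactors = FALSE)
  attr(out, "n_reflected") <- n_reflected
  if (record_candidates) {
    attr(out, "chosen_cat") <- chosen_cat
    attr(out, "pool_counts") <- pool_counts
  }
  out
}

#' Degrade a true trajectory into observed fixes
#'
#' Adds isotropic Gaussian GPS error (sd `gps_sigma`) and injects labelled
#' artifacts: outliers (a fix displaced so its arriving speed exceeds
#' 100 m/min), spikes (an extra fix inserted between two neighbours so both
#' legs run at >= 15 m/min with a 165--180 degree turn at the apex), and
#' stationary runs (extra fixes repeating the previous observed coordinate,
#' as a collar left logging indoors). Ground-truth labels are returned so
#' the filter's recall and false-removal rates can be measured.
#'
#' @param true_fixes data.frame `(animal_id, t, x, y)` of true positions.
#' @param scenario a [sim_scenario()] (rates and `gps_sigma`).
#' @return list `fixes` (observed) and `labels` (character per observed
#'   fix: `clean`, `outlier`, `spike`, `stationary`).
#' @export
degrade <- function(true_fixes, scenario) {
  rates <- c(scenario$outlier_rate, scenario$spike_rate,
             scenario$stationary_run_rate)
  if (any(rates < 0 | rates > 1)) stop("artifact rates must be in [0, 1]")
  n <- nrow(true_fixes)
  obs <- true_fixes
  obs$x <- obs$x + stats::rnorm(n, 0, scenario$gps_sigma)
  obs$y <- obs$y + stats::rnorm(n, 0, scenario$gps_sigma)
  label <- rep("clean", n)

  # outliers: displace a fix so the speed implied from its predecessor
  # exceeds the 100 m/min ceiling
  if (scenario$outlier_rate > 0 && n >= 2) {
    cand <- which(stats::runif(n - 1) < scenario$outlier_rate) + 1L
    for (i in cand) {
      dt <- as.numeric(difftime(obs$t[i], obs$t[i - 1], units = "mins"))
      ang <- stats::runif(1, 0, 2 * pi)
      d <- 100 * dt * stats::runif(1, 1.5, 3)
      obs$x[i] <- obs$x[i - 1] + d * cos(ang)
      obs$y[i] <- obs$y[i - 1] + d * sin(ang)
      label[i] <- "outlier"
    }
  }

  rows <- lapply(seq_len(n), function(i) {
    list(t = obs$t[i], x = obs$x[i], y = obs$y[i], label = label[i])
  })

  # spikes: insert an apex between i and i+1 such that both legs are fast
  # and the turn is a near-reversal
  if (scenario$spike_rate > 0 && n >= 2) {
    ins <- which(stats::runif(n - 1) < scenario$spike_rate)
    for (i in rev(ins)) {
      if (label[i] != "clean" || label[i + 1] != "clean") next
      a <- rows[[i]]; c_ <- rows[[i + 1]]
      dt <- as.numeric(difftime(c_$t, a$t, units = "mins"))
      if (dt < 0.5) next
      dt_half <- dt / 2
      mx <- (a$x + c_$x) / 2; my <- (a$y + c_$y) / 2
      ac <- sqrt((c_$x - a$x)^2 + (c_$y - a$y)^2)
      D <- max(20 * dt_half, 4 * ac)
      ang <- stats::runif(1, 0, 2 * pi)
      apex <- list(t = a$t + dt_half * 60,
                   x = mx + D * cos(ang), y = my + D * sin(ang),
                   label = "spike")
      rows <- append(rows, list(apex), after = i)
    }
  }

  # stationary runs: repeat the previous coordinate r in {2..4} extra times
  # at intermediate timestamps
  if (scenario$stationary_run_rate > 0) {
    i <- 1L
    while (i < length(rows)) {
      if (rows[[i]]$label == "clean" && rows[[i + 1]]$label == "clean" &&
          stats::runif(1) < scenario$stationary_run_rate) {
        dt <- as.numeric(difftime(rows[[i + 1]]$t, rows[[i]]$t,
                                  units = "mins"))
        r <- sample(2:4, 1)
        if (dt > (r + 1)) {
          extra <- lapply(seq_len(r), function(j) {
            list(t = rows[[i]]$t + j * dt / (r + 1) * 60,
                 x = rows[[i]]$x, y = rows[[i]]$y, label = "stationary")
          })
          rows <- append(rows, extra, after = i)
          i <- i + r
        }
      }
      i <- i + 1L
    }
  }

  tzone <- attr(true_fixes$t, "tzone")
  if (is.null(tzone)) tzone <- ""
  fixes <- data.frame(
    animal_id = true_fixes$animal_id[1],
    t = as.POSIXct(vapply(rows, function(r) as.numeric(r$t), numeric(1)),
                   origin = "1970-01-01", tz = tzone),
    x = vapply(rows, function(r) r$x, numeric(1)),
    y = vapply(rows, function(r) r$y, numeric(1)),
    stringsAsFactors = FALSE)
  list(fixes = fixes, labels = vapply(rows, function(r) r$label,
                                      character(1)))
}

#' Simulate a full multi-animal data set
#'
#' Landscape, true trajectories and degraded observations for every animal
#' in the scenario, under one seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list `landscape`, `true` (per-animal list), `observed`
#'   (data.frame over all animals), `labels` (per observed fix).
#' @export
simulate_dataset <- function(scenario) {
  pc <- scenario$patch_cells
  if (is.null(pc)) pc <- 400
  landscape <- generate_landscape(scenario$landscape_prop, scenario$extent,
                                  scenario$cell, seed = scenario$rng_seed,
                                  patch_cells = pc)
  set.seed(scenario$rng_seed + 1L)
  spread <- scenario$start_spread_days
  if (is.null(spread)) spread <- 0
  starts <- as.POSIXct("2021-05-01 06:00:00", tz = "") +
    round(stats::runif(scenario$n_animals, 0, spread)) * 86400
  true <- vector("list", scenario$n_animals)
  obs <- vector("list", scenario$n_animals)
  labels <- vector("list", scenario$n_animals)
  for (a in seq_len(scenario$n_animals)) {
    true[[a]] <- simulate_trajectory(scenario, landscape, a, t0 = starts[a])
    dg <- degrade(true[[a]], scenario)
    obs[[a]] <- dg$fixes
    labels[[a]] <- dg$labels
  }
  list(landscape = landscape, true = true,
       observed = do.call(rbind, obs), labels = unlist(labels))
}

#' Simulate a used/available table from a known selection model
#'
#' Generates point records directly from the binomial RSF model (logit
#' P(used) = alpha + b_animal + beta * in-habitat), the well-specified
#' setting in which the fitted selection coefficient should recover `beta`
#' with nominal CI coverage.
#'
#' @param n_animals number of animals.
#' @param n_points points per animal.
#' @param beta true in-habitat log-odds contrast.
#' @param alpha baseline log-odds of the used label.
#' @param p_inhab fraction of points falling in the focal habitat.
#' @param ranef_sd sd of the per-animal random intercept.
#' @param seed integer seed.
#' @return data.frame `(animal_id, x, y, used, habitat, scale)` compatible
#'   with [fit_habitat_model()]; the focal habitat is `"focal"`, the rest
#'   `"other"`.
#' @export
simulate_rsf_points <- function(n_animals = 6, n_points = 600, beta = 0.36,
                                alpha = -1, p_inhab = 0.4, ranef_sd = 0.2,
                                seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_animals), function(a) {
    b <- stats::rnorm(1, 0, ranef_sd)
    inhab <- stats::rbinom(n_points, 1, p_inhab)
    eta <- alpha + b + beta * inhab
    used <- stats::rbinom(n_points, 1, stats::plogis(eta))
    data.frame(animal_id = paste0("cat", a),
               x = stats::runif(n_points), y = stats::runif(n_points),
               used = used,
               habitat = ifelse(inhab == 1, "focal", "other"),
               scale = "sim", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rsf_design", class(out))
  out
}

#' Generate a synthetic urban road network
#'
#' A rectangular street grid of minor roads at `street_spacing` plus
#' `n_major` straight major roads crossing the extent, with small vertex
#' jitter so segments are not axis-perfect. Lengths are metres in the
#' landscape plane.
#'
#' @param extent side length of the square extent, metres.
#' @param street_spacing distance between minor streets, metres.
#' @param n_major number of major roads.
#' @param jitter sd of vertex jitter, metres.
#' @param seed integer seed.
#' @return a `roam_roads`.
#' @export
generate_roads <- function(extent = 1000, street_spacing = 150,
                           n_major = 1, jitter = 3, seed = 1) {
  set.seed(seed)
  feats <- list()
  pos <- seq(street_spacing / 2, extent - street_spacing / 2,
             by = street_spacing)
  verts <- seq(0, extent, length.out = 9)
  for (p in pos) {
    feats[[length(feats) + 1L]] <- list(
      coords = cbind(verts, p + stats::rnorm(length(verts), 0, jitter)),
      class = "minor")
    feats[[length(feats) + 1L]] <- list(
      coords = cbind(p + stats::rnorm(length(verts), 0, jitter), verts),
      class = "minor")
  }
  for (m in seq_len(n_major)) {
    y0 <- stats::runif(1, 0.2, 0.8) * extent
    y1 <- stats::runif(1, 0.2, 0.8) * extent
    feats[[length(feats) + 1L]] <- list(
      coords = cbind(verts, seq(y0, y1, length.out = length(verts)) +
                       stats::rnorm(length(verts), 0, jitter)),
      class = "major")
  }
  structure(feats, class = "roam_roads")
}

#' Simulate an owner-rated personality survey
#'
#' 43 Likert items (1--7) over the five owner-rated personality domains,
#' 13 of them loading on a latent neuroticism trait per animal; the item
#' map assigning items to domains is returned alongside, as it would
#' accompany a real survey instrument.
#'
#' @param n_animals number of animals.
#' @param seed integer seed.
#' @param loading latent-trait loading of the neuroticism items.
#' @return list `survey` (data.frame animal_id + 43 item columns),
#'   `item_map` (data.frame item, domain), `latent` (true neuroticism,
#'   standardized scale).
#' @export
simulate_survey <- function(n_animals, seed = 1, loading = 1.2) {
  set.seed(seed)
  domains <- c(rep("neuroticism", 13), rep("extraversion", 8),
               rep("agreeableness", 8), rep("dominance", 7),
               rep("impulsiveness", 7))
  items <- paste0("item", sprintf("%02d", seq_along(domains)))
  latent <- stats::rnorm(n_animals)
  clip <- function(v) pmin(7L, pmax(1L, as.integer(round(v))))
  survey <- data.frame(animal_id = paste0("cat", seq_len(n_animals)))
  for (j in seq_along(items)) {
    base <- if (domains[j] == "neuroticism")
      4 + loading * latent else stats::runif(1, 2.5, 5.5)
    survey[[items[j]]] <- clip(base + stats::rnorm(n_animals, 0, 1))
  }
  list(survey = survey,
       item_map = data.frame(item = items, domain = domains),
       latent = latent)
}
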