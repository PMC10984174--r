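# Shared builders and independent oracles used across the suite. Oracles
# deliberately take a different computational route from the package code
# they check.

# trajectory data.frame from minute offsets and coordinates
make_traj <- function(mins, x, y, id = "cat1",
                      t0 = as.POSIXct("2021-06-01 08:00:00", tz = "")) {
  data.frame(animal_id = id, t = t0 + mins * 60, x = x, y = y,
             stringsAsFactors = FALSE)
}

# Snyder/Thomas series forward transverse Mercator: an independent
# formulation of the UTM forward map (the package uses the Krueger series)
snyder_utm <- function(lon, lat, zone = 17) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lam0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180; lam <- lon * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))
  x <- 500000 + k0 * N * (A + (1 - T + C) * A^3 / 6 +
                            (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
                                   (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                                   (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  c(x = x, y = y)
}

# brute-force speed-filter oracle: smallest removal set (over all subsets)
# after which no arriving speed exceeds the threshold; NULL when not unique
bruteforce_speed_filter <- function(traj, threshold) {
  n <- nrow(traj)
  ok <- function(keep) {
    if (length(keep) < 2) return(TRUE)
    dt <- diff(as.numeric(traj$t[keep])) / 60
    d <- sqrt(diff(traj$x[keep])^2 + diff(traj$y[keep])^2)
    all(d / dt <= threshold)
  }
  best <- NULL
  for (size in 0:n) {
    sets <- utils::combn(n, size, simplify = FALSE)
    good <- Filter(function(rm) ok(setdiff(seq_len(n), rm)), sets)
    if (length(good)) { best <- good; break }
  }
  if (length(best) == 1) sort(best[[1]]) else NULL
}

# full 2^n sign-enumeration oracle for the signed-rank test
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  list(statistic = w_obs, p.value = min(1, 2 * min(p_lo, p_hi)))
}

# hand-rolled IRLS for the gamma/log-link mean model: independent of
# stats::glm (for the log link the working weights are constant)
irls_gamma_log <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- qr.solve(X, log(y))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- qr.solve(X, z)
    if (max(abs(beta_new - beta)) < tol) break
    beta <- beta_new
  }
  as.numeric(beta)
}

# four-category study landscape at a small extent, deterministic per seed
test_landscape <- function(seed = 1, extent = 300, cell = 5,
                           patch_cells = 50) {
  generate_landscape(c(impervious = 0.66, road = 0.26, greenspace = 0.06,
                       agriculture = 0.02),
                     extent = extent, cell = cell, seed = seed,
                     patch_cells = patch_cells)
}

# scenario used by the filter-recovery simulations: default movement with
# artifacts injected at the chosen study rates
artifact_scenario <- function(seed, duration_days = 6) {
  sim_scenario(n_animals = 1, outlier_rate = 0.01, spike_rate = 0.01,
               stationary_run_rate = 0.02, duration_days = duration_days,
               rng_seed = seed)
}
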