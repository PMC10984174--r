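test_that("MCP of a 100 m square is exactly 1 ha, interior points ignored", {
  sq <- data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  expect_equal(mcp(sq)$area_ha, 1.0)
  withins <- rbind(sq, data.frame(x = runif(20, 10, 90),
                                  y = runif(20, 10, 90)))
  expect_equal(mcp(withins)$area_ha, 1.0)
  expect_equal(nrow(mcp(withins)$polygons[[1]]), 4)
})

test_that("MCP area is invariant under rigid motion", {
  set.seed(5)
  fx <- data.frame(x = rnorm(200, 0, 40), y = rnorm(200, 0, 40))
  a0 <- mcp(fx)$area_ha
  th <- 0.7
  rot <- data.frame(x = cos(th) * fx$x - sin(th) * fx$y + 500,
                    y = sin(th) * fx$x + cos(th) * fx$y - 200)
  expect_lt(abs(mcp(rot)$area_ha / a0 - 1), 1e-6)
})

test_that("MCP contains every fix and hull area bounds hold on a disc", {
  set.seed(6)
  r <- 350 * sqrt(runif(1000)); th <- runif(1000, 0, 2 * pi)
  fx <- data.frame(x = r * cos(th), y = r * sin(th))
  est <- mcp(fx)
  expect_true(all(point_in_convex(fx$x, fx$y, est$polygons[[1]])))
  expect_gt(est$area_ha, 30)
  expect_lt(est$area_ha, pi * 350^2 / 1e4)   # 38.48 ha disc
})

test_that("degenerate fix sets are rejected", {
  expect_error(mcp(data.frame(x = c(0, 1), y = c(0, 1))), "degenerate")
  expect_error(mcp(data.frame(x = 0:5, y = 0:5)), "degenerate hull")
})

test_that("KDE isopleths match the bivariate-normal closed form", {
  set.seed(42)
  n <- 10000
  fx <- data.frame(x = rnorm(n, 0, 10), y = rnorm(n, 0, 10))
  # smoothed density is N(0, (sigma^2 + h^2) I); chi^2_2 quantiles give the
  # exact isopleth areas
  h <- 1
  sig2 <- 10^2 + h^2
  a95 <- kde_isopleth(fx, 95, bandwidth = h, grid = 200)$area_ha * 1e4
  a50 <- kde_isopleth(fx, 50, bandwidth = h, grid = 200)$area_ha * 1e4
  expect_lt(abs(a95 / (pi * sig2 * qchisq(0.95, 2)) - 1), 0.05)
  expect_lt(abs(a50 / (pi * sig2 * qchisq(0.50, 2)) - 1), 0.05)
})

test_that("the 50% isopleth nests inside the 95% for any input", {
  set.seed(9)
  fx <- data.frame(x = c(rnorm(150, 0, 20), rnorm(150, 120, 35)),
                   y = c(rnorm(150, 0, 25), rnorm(150, -60, 30)))
  a95 <- kde_isopleth(fx, 95)$area_ha
  a50 <- kde_isopleth(fx, 50)$area_ha
  expect_lt(a50, a95)
})

test_that("KDE isopleth area converges to the closed form as n grows", {
  h <- 2
  err <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    fx <- data.frame(x = rnorm(n, 0, 10), y = rnorm(n, 0, 10))
    a <- kde_isopleth(fx, 95, bandwidth = h, grid = 150)$area_ha * 1e4
    abs(a / (pi * (100 + h^2) * qchisq(0.95, 2)) - 1)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.05)
})

test_that("KDE input validation", {
  expect_error(kde_isopleth(data.frame(x = rep(1, 6), y = rep(2, 6)), 95,
                            bandwidth = 1), "zero variance")
  expect_error(kde_isopleth(data.frame(x = 1:3, y = 1:3), 95), "nrow")
})

test_that("day/night split respects the clock boundaries and partitions", {
  t0 <- as.POSIXct("2021-06-01 00:00:00", tz = "")
  stamps <- t0 + c(5 * 3600 + 59 * 60,            # 05:59 night
                   6 * 3600,                      # 06:00 day
                   17 * 3600 + 59 * 60 + 59,      # 17:59:59 day
                   18 * 3600)                     # 18:00 night
  fx <- data.frame(animal_id = "c", t = stamps, x = 1:4, y = 1:4)
  sp <- split_day_night(fx)
  expect_equal(sp$day$x, c(2, 3))
  expect_equal(sp$night$x, c(1, 4))
  expect_equal(nrow(sp$day) + nrow(sp$night), nrow(fx))
  expect_length(intersect(sp$day$x, sp$night$x), 0)
})

test_that("asymptote curve is monotone; revisited bounds plateau, spirals do not", {
  # all later fixes inside the early square: constant after the corners
  sq <- make_traj(0:19, c(0, 100, 100, 0, runif(16, 10, 90)),
                  c(0, 0, 100, 100, runif(16, 10, 90)))
  res <- asymptote_curve(sq, step = 1)
  expect_true(all(diff(res$curve$area_ha) >= -1e-12))
  expect_true(res$plateau)
  expect_equal(max(res$curve$area_ha), 1.0)
  # outward spiral keeps growing
  i <- 0:39
  spiral <- make_traj(i, (10 + 8 * i) * cos(i / 3), (10 + 8 * i) * sin(i / 3))
  res2 <- asymptote_curve(spiral, step = 1)
  expect_true(all(diff(res2$curve$area_ha) >= -1e-12))
  expect_false(res2$plateau)
})

test_that("equivalent-circle diameter and buffer reproduce the reference derivation", {
  d <- equivalent_circle_diameter(38.45)
  expect_equal(d$diameter_m, 700)
  expect_equal(buffer_distance(38.45, 0.20)$buffer_m, 840)
  # circle of radius 50 m has area 0.7853982 ha and diameter 100 m
  expect_equal(equivalent_circle_diameter(pi * 50^2 / 1e4)$diameter_m, 100)
  # zero margin: buffer equals the diameter exactly
  for (a in c(0.5, 4.4, 38.45))
    expect_identical(buffer_distance(a, 0)$buffer_m,
                     equivalent_circle_diameter(a)$diameter_m)
  expect_error(equivalent_circle_diameter(0), "positive")
})

test_that("signed-rank test matches the sign-enumeration oracle", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0)),
               list(statistic = 6, p.value = 0.25, n_used = 3L,
                    exact = TRUE))
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0, 3), sample(0:1, 1))  # ties and zeros likely
    got <- wilcoxon_signed_rank(d, rep(0, n))
    if (got$n_used == 0) next
    oracle <- enumerate_signed_rank(d)
    expect_equal(got$statistic, oracle$statistic)
    expect_equal(got$p.value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank exact p agrees with the reference implementation when untied", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(6:11, 1)
    d <- rnorm(n)   # continuous: no ties, no zeros
    got <- wilcoxon_signed_rank(d, rep(0, n))
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("antisymmetric differences sit at the null centre with p = 1", {
  got <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_equal(got$p.value, 1)
  expect_warning(res <- wilcoxon_signed_rank(c(1, 1), c(1, 1)), "zero")
  expect_equal(res$p.value, 1)
})

test_that("large-sample signed-rank p approximates the exact one", {
  set.seed(29)
  d <- rnorm(30, 0.3)
  approx <- wilcoxon_signed_rank(d, rep(0, 30))
  expect_false(approx$exact)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(approx$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Brown-Forsythe is location invariant and matches hand computation", {
  bf <- brown_forsythe(c(1, 2, 3), c(11, 12, 13))
  expect_equal(bf$statistic, 0)
  expect_equal(brown_forsythe(c(4, 7, 9), c(4, 7, 9))$statistic, 0)
  # hand computation on a small fixture
  a <- c(1, 4, 6, 10); b <- c(2, 3, 9)
  za <- abs(a - median(a)); zb <- abs(b - median(b))
  z <- c(za, zb); g <- rep(1:2, c(4, 3))
  ssb <- sum(tapply(z, g, length) * (tapply(z, g, mean) - mean(z))^2)
  ssw <- sum((z - ave(z, g))^2)
  f_hand <- (ssb / 1) / (ssw / 5)
  got <- brown_forsythe(a, b)
  expect_equal(got$statistic, f_hand, tolerance = 1e-12)
  expect_equal(got$df1, 1); expect_equal(got$df2, 5)
})

test_that("Brown-Forsythe agrees with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(3)
  a <- rnorm(12, 0, 1); b <- rnorm(15, 2, 2.5)
  got <- brown_forsythe(a, b)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(12, 15))),
                         center = median)
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p.value, ref$`Pr(>F)`[1], tolerance = 1e-12)
})
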