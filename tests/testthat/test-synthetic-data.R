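test_that("identical configurations give bit-identical output", {
  cfg <- simConfig(seed = 9, n_individuals = 2, n_days = 120)
  a <- simulateTracks(cfg)
  b <- simulateTracks(cfg)
  expect_identical(a$locations, b$locations)
  expect_identical(a$truth, b$truth)
  # and the global RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulateTracks(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("degenerate migration probability yields resident-only truth", {
  sim <- simulateTracks(simConfig(seed = 2, n_individuals = 3, n_days = 400,
                                  p_migrate_per_winter = 0))
  for (tr in sim$truth) {
    expect_null(tr$migrations)
    expect_true(all(tr$phases$phase == "breeding"))
  }
})

test_that("with no injected outliers every consecutive speed is plausible", {
  sim <- simulateTracks(simConfig(seed = 4, n_individuals = 2, n_days = 380,
                                  p_migrate_per_winter = 1, outlier_rate = 0))
  for (id in unique(sim$locations$individual_id)) {
    sub <- sim$locations[sim$locations$individual_id == id, ]
    n <- nrow(sub)
    d <- haversineM(sub$lon[-n], sub$lat[-n], sub$lon[-1], sub$lat[-1])
    dt <- diff(as.numeric(sub$timestamp))
    expect_true(all(d / dt <= 30))
  }
})

test_that("injected outliers violate the speed ceiling and are flagged", {
  sim <- simulateTracks(simConfig(seed = 4, n_individuals = 1, n_days = 120,
                                  outlier_rate = 0.02))
  loc <- sim$locations
  idx <- which(loc$outlier)
  expect_gt(length(idx), 0)
  d <- haversineM(loc$lon[idx - 1], loc$lat[idx - 1], loc$lon[idx], loc$lat[idx])
  dt <- as.numeric(loc$timestamp[idx]) - as.numeric(loc$timestamp[idx - 1])
  expect_true(all(d / dt > 30))
})

test_that("the generator's event log matches the configured stopover plan", {
  sim <- simulateTracks(simConfig(seed = 1, n_individuals = 5, n_days = 250,
                                  p_migrate_per_winter = 1,
                                  stopover_count_range = c(2L, 2L),
                                  stopover_days_range = c(4L, 4L)))
  for (tr in sim$truth) {
    aut <- tr$stopovers[tr$stopovers$season == "autumn_migration", ]
    expect_equal(nrow(aut), 2)
    expect_true(all(aut$duration_days >= 3))
  }
})

test_that("every fix lies within 3 error-sd of its true position", {
  cfg <- simConfig(seed = 6, n_individuals = 2, n_days = 150, source = "argos")
  sim <- simulateTracks(cfg)
  loc <- sim$locations
  d <- haversineM(loc$lon, loc$lat, loc$true_lon, loc$true_lat)
  sdm <- cfg$argos_lc_error_m[loc$lc]
  expect_true(all(d <= 3 * sdm + 1))  # 1 m slack for projection arithmetic
})

test_that("stationary-phase anchors stay within the configured site radius", {
  cfg <- simConfig(seed = 6, n_individuals = 2, n_days = 200,
                   p_migrate_per_winter = 1)
  sim <- simulateTracks(cfg)
  for (tr in sim$truth) {
    b <- tr$sites[tr$sites$site_id == "B", ]
    days <- tr$plan[tr$plan$type == "stationary" & tr$plan$site_id %in% "B", ]
    d <- haversineM(days$slon, days$slat, b$lon, b$lat) / 1000
    expect_true(all(d <= cfg$breeding_radius_km))
  }
})

test_that("inconsistent site geometry is a configuration error", {
  expect_error(simConfig(breeding_center = c(8, 50), winter_center = c(8, 50.01),
                         breeding_radius_km = 5, p_migrate_per_winter = 0.5),
               "winter center")
  expect_error(simConfig(p_migrate_per_winter = 1.4), "probabilities")
  expect_error(simConfig(stopover_days_range = c(1, 2), stopover_min_days = 3),
               "stopover_days_range")
})

test_that("synthetic land cover partitions the extent as constructed", {
  g <- simulateLandcover(c(-1, 1, -2, 2), 0.02, c(0, 0), 111.3195)
  # city-centre cell is artificial (green urban patch is level-1 artificial)
  expect_true(gridLookup(g, 0, 0) %in% c(112, 141))
  # class proportions partition the extent
  tab <- table(g$values)
  expect_equal(sum(tab) / length(g$values), 1)
  # circle-in-rectangle oracle: radius of one degree on a 2 x 4 degree
  # equatorial extent covers pi/8 of the cells
  artificial <- mean(g$values %/% 100 == 1)
  expect_equal(artificial, pi / 8, tolerance = 0.02)
  expect_error(simulateLandcover(c(0, 0, 0, 1), 0.1, c(0, 0.5), 5),
               "zero-area")
})

test_that("land cover round-trips through the ESRI ASCII grid format", {
  g <- simulateLandcover(c(8, 9, 50, 51), 0.05, c(8.5, 50.5), 10)
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, f)
  g2 <- readAsciiGrid(f)
  expect_equal(g2$values, g$values, ignore_attr = TRUE)
  expect_equal(g2$cellsize, g$cellsize)
  expect_equal(gridLookup(g2, 8.5, 50.5), gridLookup(g, 8.5, 50.5))
})

test_that("simulated ring recoveries follow the configured proportions", {
  # degenerate: nothing abroad
  r0 <- simulateRingRecoveries(50, p_abroad = 0, seed = 3)
  expect_true(all(r0$recovery_country == "DE"))
  # binomial oracle at p = 0.72
  r1 <- simulateRingRecoveries(1000, p_abroad = 0.72, seed = 3)
  expect_lt(abs(mean(r1$recovery_country != "DE") - 0.72),
            3 * sqrt(0.72 * 0.28 / 1000))
  expect_error(simulateRingRecoveries(10, country_weights = c(FR = 0.5)),
               "sum to 1")
})

test_that("injected filter violations are rejected at the configured rate", {
  rec <- simulateRingRecoveries(1000, seed = 8, violation_rate = 0.2)
  out <- filterRecoveries(rec)
  expect_equal(mean(out$verdict == "kept"), 0.8, tolerance = 0.02)
  # each injected violation is caught for the injected reason
  v <- out[out$truth_violation != "none", ]
  expect_true(all(v$verdict == "dropped"))
  expect_true(all(v$reason == v$truth_violation))
  # clean records are all kept
  expect_true(all(out$verdict[out$truth_violation == "none"] == "kept"))
})
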