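test_that("boundary dates follow the midpoint and 14-day gap rules", {
  # symmetric two-day gap: the middle day
  expect_equal(formatFracDate(boundaryDate(as.Date("2011-03-16"),
                                           as.Date("2011-03-18"))),
               "2011-03-17")
  # seven-day gap: fractional midpoint
  bd <- boundaryDate(as.Date("2009-03-11"), as.Date("2009-03-18"))
  expect_equal(bd, as.numeric(as.Date("2009-03-14")) + 0.5)
  expect_equal(formatFracDate(bd), "2009-03-14.5")
  # a 38-day gap is excluded
  expect_true(is.na(boundaryDate(as.Date("2013-10-25"), as.Date("2013-12-02"))))
  # exactly 14 days is not excluded
  expect_false(is.na(boundaryDate(as.Date("2010-09-27"), as.Date("2010-10-11"))))
  expect_error(boundaryDate(as.Date("2011-03-18"), as.Date("2011-03-16")),
               "precedes")
})

test_that("the common day-of-year scale is leap-aware", {
  expect_equal(doy365(as.Date("2019-03-01")), 60)
  expect_equal(doy365(as.Date("2020-03-01")), 60)  # same position in a leap year
  expect_equal(doy365(as.Date("2020-02-29")), 59.5)
  expect_equal(doy365(as.numeric(as.Date("2010-10-26")) + 0.5), 299.5)
})

test_that("stationary runs aggregate into sites as constructed", {
  set.seed(21)
  one <- clusterTracks(8.68, 50.58, "2019-06-01", 30)
  runs <- detectStationarySites(one)
  expect_equal(sum(runs$is_site), 1)
  # two 30-day clusters 300 km apart are two sites
  two <- rbind(clusterTracks(8.68, 50.58, "2019-06-01", 30),
               clusterTracks(4.45, 50.58, "2019-07-10", 30))
  runs2 <- detectStationarySites(two)
  expect_equal(sum(runs2$is_site), 2)
  expect_equal(nrow(detectStationarySites(one[0, ])), 0)
})

test_that("site centres are recovered near truth on simulated tracks", {
  cfg <- simConfig(seed = 31, n_individuals = 2, n_days = 380,
                   p_migrate_per_winter = 1, gps_interval_min = 120,
                   n_winter_sites_range = c(1L, 1L))
  sim <- simulateTracks(cfg)
  for (id in names(sim$truth)) {
    tr <- sim$truth[[id]]
    runs <- detectStationarySites(sim$locations[
      sim$locations$individual_id == id, ])
    siteRuns <- runs[runs$is_site & runs$span_days >= 20, ]
    for (s in seq_len(nrow(tr$sites))) {
      d <- haversineM(siteRuns$center_lon, siteRuns$center_lat,
                      tr$sites$lon[s], tr$sites$lat[s]) / 1000
      expect_lt(min(d), 5)
    }
  }
})

test_that("a resident bird yields a single breeding phase and no migration", {
  sim <- simulateTracks(simConfig(seed = 32, n_individuals = 1, n_days = 380,
                                  p_migrate_per_winter = 0,
                                  gps_interval_min = 120))
  seg <- segmentAnnualCycle(sim$locations)
  expect_true(all(seg$phases$phase == "breeding"))
  expect_equal(nrow(seg$phases), 1)
  expect_null(seg$stopovers)
})

test_that("a migrant's stopovers and boundaries track the generator truth", {
  cfg <- simConfig(seed = 33, n_individuals = 1, n_days = 300,
                   p_migrate_per_winter = 1, gps_interval_min = 60,
                   stopover_count_range = c(2L, 2L),
                   stopover_days_range = c(4L, 4L),
                   n_winter_sites_range = c(1L, 1L))
  sim <- simulateTracks(cfg)
  seg <- segmentAnnualCycle(sim$locations)
  tr <- sim$truth$bird01
  aut <- seg$phases[seg$phases$phase == "autumn_migration", ]
  expect_equal(nrow(aut), 1)
  so <- seg$stopovers[seg$stopovers$season == "autumn_migration", ]
  expect_equal(nrow(so), 2)
  expect_true(all(so$duration_days >= 3))
  # onset and arrival midpoints within one day of truth
  ph <- seg$phases
  r <- which(ph$phase == "autumn_migration")
  onset <- boundaryDate(as.Date(ph$last_signal[r - 1]),
                        as.Date(ph$first_signal[r]))
  arrive <- boundaryDate(as.Date(ph$last_signal[r]),
                         as.Date(ph$first_signal[r + 1]))
  m <- tr$migrations[tr$migrations$season == "autumn_migration", ]
  expect_lte(abs(onset - as.numeric(m$dep_date)), 1)
  expect_lte(abs(arrive - as.numeric(m$arr_date)), 1)
})

test_that("a 60-km displacement is a site shift, not migration", {
  set.seed(34)
  two <- rbind(clusterTracks(8.68, 50.58, "2019-06-01", 120),
               clusterTracks(8.68, 50.04, "2019-09-29", 90))  # ~60 km south
  seg <- segmentAnnualCycle(two)
  expect_false(any(grepl("migration", seg$phases$phase)))
  expect_equal(nrow(seg$shifts), 1)
  expect_equal(seg$shifts$distance_km, 60, tolerance = 0.05)
})

test_that("raising the migration threshold never adds migration intervals", {
  cfg <- simConfig(seed = 35, n_individuals = 3, n_days = 300,
                   p_migrate_per_winter = 1, gps_interval_min = 120)
  sim <- simulateTracks(cfg)
  counts <- sapply(c(50, 100, 200, 400), function(th) {
    seg <- segmentAnnualCycle(sim$locations, min_migration_km = th)
    sum(grepl("migration", seg$phases$phase))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("phase intervals are non-overlapping and ordered per individual", {
  cfg <- simConfig(seed = 36, n_individuals = 2, n_days = 380,
                   p_migrate_per_winter = 1, gps_interval_min = 120)
  seg <- segmentAnnualCycle(simulateTracks(cfg)$locations)
  for (id in unique(seg$phases$individual_id)) {
    ph <- seg$phases[seg$phases$individual_id == id, ]
    expect_true(all(ph$first_signal <= ph$last_signal))
    if (nrow(ph) > 1)
      expect_true(all(diff(as.numeric(ph$first_signal)) > 0))
    expect_true(all(head(ph$last_signal, -1) <= tail(ph$first_signal, -1)))
  }
})

test_that("duration summaries use leap-aware calendar arithmetic", {
  ph <- data.frame(
    individual_id = c("a", "b", "c", "d"),
    phase = "autumn_migration",
    first_signal = as.Date(c("2019-10-21", "2019-11-16", "2019-10-23",
                             "2019-10-20")),
    last_signal = as.Date(c("2019-11-21", "2019-12-02", "2019-11-29",
                            "2019-11-15")))
  d <- phenologyDurations(ph, "autumn_migration")
  expect_equal(d$durations, c(31, 16, 37, 26))
  expect_equal(d$mean, 27.5)
  expect_equal(d$sd, 8.9)
  # a span across 29 Feb 2020 counts the leap day
  lp <- data.frame(individual_id = "x", phase = "wintering",
                   first_signal = as.Date("2019-12-02"),
                   last_signal = as.Date("2020-03-27"))
  expect_equal(phenologyDurations(lp, "wintering")$durations, 116)
  # single interval: mean is the value, sd is absent
  one <- phenologyDurations(ph[1, ], "autumn_migration")
  expect_equal(one$mean, 31)
  expect_true(is.na(one$sd))
})

test_that("phenology summary excludes gap violations and handles empties", {
  ph <- woodpigeonPhases()
  arg <- ph[ph$data_type == "Argos", ]
  s <- phenologySummary(arg, "autumn_arrival")
  expect_equal(s$n_excluded, 1L)  # the 38-day transmission gap
  empty <- phenologySummary(arg[arg$phase == "breeding", ], "autumn_departure")
  expect_equal(empty$n, 0L)
})

test_that("the wintering-site inventory counts distinct sites per winter", {
  cfg <- simConfig(seed = 37, n_individuals = 1, n_days = 300,
                   p_migrate_per_winter = 1, gps_interval_min = 120,
                   n_winter_sites_range = c(3L, 3L),
                   winter_site_shift_km = c(30, 60))
  sim <- simulateTracks(cfg)
  seg <- segmentAnnualCycle(sim$locations)
  inv <- siteInventory(seg)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$n_sites, 3)
  expect_true(inv$multi_site)
  # the first-occupied site is the one closest in time to arrival
  tr <- sim$truth$bird01
  w1 <- tr$sites[tr$sites$site_id == "W1.1", ]
  expect_lt(haversineM(inv$first_site_lon, inv$first_site_lat,
                       w1$lon, w1$lat) / 1000, 5)
  # a resident has no wintering sites
  res <- segmentAnnualCycle(simulateTracks(
    simConfig(seed = 38, n_individuals = 1, n_days = 300,
              p_migrate_per_winter = 0, gps_interval_min = 240))$locations)
  expect_equal(nrow(siteInventory(res)), 0)
})
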