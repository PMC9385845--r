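mkRecord <- function(ring_date, rec_date, rec_country = "FR", accuracy = 0,
                     ring_country = "DE", rec_lon = 0.2, rec_lat = 44.5) {
  data.frame(ring_id = "R1", ring_date = as.Date(ring_date),
             ring_lon = 8.7, ring_lat = 50.6, ring_country = ring_country,
             recovery_date = as.Date(rec_date), recovery_lon = rec_lon,
             recovery_lat = rec_lat, recovery_country = rec_country,
             date_accuracy_days = accuracy, stringsAsFactors = FALSE)
}

test_that("the seasonal, span and accuracy filters apply the stated windows", {
  # ringed DE mid-June, recovered FR mid-December two years on: kept
  expect_equal(filterRecoveries(mkRecord("2000-06-15", "2002-12-15"))$verdict,
               "kept")
  # ringed before the breeding window opens
  expect_equal(filterRecoveries(mkRecord("2000-03-15", "2002-12-15"))$reason,
               "season")
  # span above five years
  expect_equal(filterRecoveries(mkRecord("2000-06-15", "2006-12-15"))$reason,
               "span")
  # date accuracy worse than six weeks
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2002-12-15", accuracy = 43))$reason, "accuracy")
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2002-12-15", accuracy = 42))$verdict, "kept")
})

test_that("the Germany window ends with February, the European one on 30 March", {
  # "30 February" read as end of month: Feb 28 within DE is in season
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2003-02-28", "DE", rec_lon = 9, rec_lat = 51))$verdict,
    "kept")
  # March recovery within DE is out of season
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2003-03-15", "DE", rec_lon = 9, rec_lat = 51))$reason,
    "season")
  # abroad: 30 March in, 31 March out
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2003-03-30"))$verdict, "kept")
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2003-03-31"))$reason, "season")
  # October recovery only valid abroad
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2002-10-15"))$verdict, "kept")
  expect_equal(filterRecoveries(
    mkRecord("2000-06-15", "2002-10-15", "DE", rec_lon = 9,
             rec_lat = 51))$reason, "season")
})

test_that("winter-ringed birds recovered in the German breeding season are kept", {
  rec <- mkRecord("2001-12-10", "2003-06-20", rec_country = "DE",
                  ring_country = "FR", rec_lon = 9, rec_lat = 51)
  expect_equal(filterRecoveries(rec)$verdict, "kept")
})

test_that("dropped records carry one primary reason with fixed priority", {
  # violates both span and accuracy: span wins
  both <- mkRecord("2000-06-15", "2006-12-15", accuracy = 60)
  expect_equal(filterRecoveries(both)$reason, "span")
  # season outranks span and accuracy
  all3 <- mkRecord("2000-03-15", "2006-06-15", accuracy = 60)
  expect_equal(filterRecoveries(all3)$reason, "season")
  # malformed outranks everything
  bad <- mkRecord("2000-03-15", "2006-06-15", accuracy = 60)
  bad$recovery_lon <- NA
  expect_equal(filterRecoveries(bad)$reason, "malformed")
})

test_that("verdicts are independent of record order", {
  rec <- simulateRingRecoveries(200, seed = 71, violation_rate = 0.3)
  fwd <- filterRecoveries(rec)
  shuffled <- rec[sample(nrow(rec)), ]
  rev <- filterRecoveries(shuffled)
  rev <- rev[match(fwd$ring_id, rev$ring_id), ]
  expect_equal(fwd$verdict, rev$verdict)
  expect_equal(fwd$reason, rev$reason)
})

test_that("recovery lines are densified great circles of the right length", {
  rec <- mkRecord("2000-06-15", "2002-12-15")
  ln <- recoveryLines(rec, step_km = 10)
  m <- ln[[1]]
  expect_equal(unname(m[1, ]), c(8.7, 50.6))
  expect_equal(unname(m[nrow(m), ]), c(0.2, 44.5), tolerance = 1e-9)
  gc <- haversineM(8.7, 50.6, 0.2, 44.5)
  expect_equal(lineLengthsM(ln)[[1]], gc, tolerance = 1e-3)
  # vertex spacing at most 10 km
  seg <- haversineM(m[-nrow(m), "lon"], m[-nrow(m), "lat"],
                    m[-1, "lon"], m[-1, "lat"])
  expect_true(all(seg <= 10000 + 1))
  # zero-length line kept
  same <- mkRecord("2000-06-15", "2002-12-15", rec_lon = 8.7, rec_lat = 50.6)
  expect_equal(lineLengthsM(recoveryLines(same))[[1]], 0)
})

test_that("line density matches the circle-chord oracle and is linear", {
  # a long straight line through a cell centre with radius 1 km:
  # chord 2 km over the disc area pi gives 2/pi km per km^2
  ln <- structure(list(cbind(lon = c(7.5, 10.5), lat = c(50, 50))),
                  class = "recoveryLines")
  ld <- lineDensity(ln, cell_size_m = 2000, radius_m = 1000)
  expect_equal(max(ld$grid$values), 2 / pi, tolerance = 1e-3)
  # cells far from the line are zero
  expect_true(any(ld$grid$values == 0))
  # doubling the lines doubles every cell value
  ln2 <- structure(list(ln[[1]], ln[[1]]), class = "recoveryLines")
  ld2 <- lineDensity(ln2, cell_size_m = 2000, radius_m = 1000)
  expect_equal(ld2$grid$values, 2 * ld$grid$values, tolerance = 1e-9)
  expect_error(lineDensity(ln, 2000, -1), "radius")
})

test_that("recovery-position kernels resolve separate wintering clusters", {
  set.seed(72)
  a <- gaussCloud(40, sd_m = 30e3, lon0 = 0, lat0 = 44.5)
  b <- gaussCloud(40, sd_m = 30e3, lon0 = -3.7, lat0 = 39.5)  # ~700 km away
  rec <- data.frame(recovery_lon = c(a$lon, b$lon),
                    recovery_lat = c(a$lat, b$lat))
  kde <- recoveryPositionKDE(rec)
  hr95 <- kde[["95%"]]
  expect_gte(length(unique(hrCells(hr95)$component)), 2)
  # mass ordering: every 50% cell is inside the 95% set
  k50 <- paste(hrCells(kde[["50%"]])$ix, hrCells(kde[["50%"]])$iy)
  k95 <- paste(hrCells(hr95)$ix, hrCells(hr95)$iy)
  expect_true(all(k50 %in% k95))
  # a tight cluster's 50% contour contains the cluster centroid
  kdeA <- recoveryPositionKDE(data.frame(recovery_lon = a$lon,
                                         recovery_lat = a$lat))
  expect_true(pointsInHomeRange(kdeA[["50%"]], mean(a$lon), mean(a$lat)))
  expect_error(recoveryPositionKDE(rec[1:3, ]), "at least 5")
})

test_that("recovery proportions split within and outside the ringing country", {
  rec <- do.call(rbind, c(
    replicate(3, mkRecord("2000-06-15", "2002-12-15", "DE", rec_lon = 9,
                          rec_lat = 51), simplify = FALSE),
    replicate(6, mkRecord("2000-06-15", "2002-12-15", "FR"), simplify = FALSE),
    replicate(1, mkRecord("2000-06-15", "2002-12-15", "ES"), simplify = FALSE)))
  pr <- recoveryProportions(rec)
  expect_equal(pr$n, 10L)
  expect_equal(pr$p_outside, 0.7)
  expect_equal(sum(pr$abroad$fraction), 1)
  expect_equal(pr$abroad$fraction[pr$abroad$country == "FR"], 6 / 7)
  empty <- recoveryProportions(rec[0, ])
  expect_equal(empty$n, 0L)
})
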