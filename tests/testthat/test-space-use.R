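test_that("href bandwidth matches its closed form", {
  set.seed(41)
  xy <- scale(matrix(rnorm(128), 64, 2))  # sd exactly 1 per axis, n = 64
  xy <- sweep(xy, 2, attr(xy, "scaled:center"))  # plain matrix, sd 1
  expect_equal(hrefBandwidth(xy, "bivnorm"), 64^(-1 / 6), tolerance = 1e-3)
  expect_equal(hrefBandwidth(xy, "epanechnikov"), 1.77 * 64^(-1 / 6),
               tolerance = 1e-3)
  same <- matrix(1, 10, 2)
  expect_error(hrefBandwidth(same), "degenerate")
  expect_error(hrefBandwidth(xy[1:3, ]), "at least 5")
})

test_that("kernel UD mass normalizes to one and respects kernel support", {
  set.seed(42)
  pts <- gaussCloud(200)
  for (k in c("epanechnikov", "bivnorm")) {
    ud <- kernelUD(pts$lon, pts$lat, grid_cells = 80, kernel = k)
    expect_equal(sum(udDensity(ud)) * ud@cellSize^2, 1, tolerance = 1e-6)
    expect_true(all(udDensity(ud) >= 0))
  }
  # single point, fixed bandwidth: density peaks at the nearest cell and the
  # Epanechnikov support does not extend beyond h
  ud1 <- kernelUD(8.68, 50.58, grid_cells = 50, kernel = "epanechnikov",
                  h = 200)
  dens <- udDensity(ud1)
  peak <- which(dens == max(dens), arr.ind = TRUE)[1, ]
  xc <- ud1@xmin + (peak[1] - 0.5) * ud1@cellSize
  yc <- ud1@ymin + (peak[2] - 0.5) * ud1@cellSize
  p0 <- projectAEQ(8.68, 50.58, ud1@lon0, ud1@lat0)
  expect_lt(sqrt((xc - p0[1, "x"])^2 + (yc - p0[1, "y"])^2),
            ud1@cellSize * 1.5)
  on <- which(dens > 0, arr.ind = TRUE)
  dx <- ud1@xmin + (on[, 1] - 0.5) * ud1@cellSize - p0[1, "x"]
  dy <- ud1@ymin + (on[, 2] - 0.5) * ud1@cellSize - p0[1, "y"]
  expect_true(all(sqrt(dx^2 + dy^2) <= 200 + 1e-9))
  expect_error(kernelUD(pts$lon, pts$lat, h = -5), "bandwidth")
})

test_that("volume contours select descending-density cells with row-major ties", {
  ud <- uniformUD(k = 7, nx = 10)
  hr <- volumeContour(ud, 0.5)
  expect_equal(nrow(hrCells(hr)), ceiling(0.5 * 7))
  # under uniform density the first cells in linear order are selected
  expect_equal(sort(hrCells(hr)$ix + (hrCells(hr)$iy - 1) * 10), 1:4)
  expect_error(volumeContour(ud, 1.2), "level")
  # nesting of levels on a real surface
  set.seed(43)
  pts <- gaussCloud(300)
  ud2 <- kernelUD(pts$lon, pts$lat)
  expect_lte(hrArea(volumeContour(ud2, 0.5)), hrArea(volumeContour(ud2, 0.95)))
})

test_that("the 95% contour of a Gaussian sample matches the analytic area", {
  set.seed(44)
  pts <- gaussCloud(500, sd_m = 1000)
  analytic <- pi * qchisq(0.95, 2) * 1  # km^2 for sigma = 1 km
  for (k in c("epanechnikov", "bivnorm")) {
    hr <- volumeContour(kernelUD(pts$lon, pts$lat, kernel = k), 0.95)
    expect_equal(hrArea(hr), analytic, tolerance = 0.15)
  }
})

test_that("a 95% contour captures about 95% of a fresh sample", {
  set.seed(45)
  hr <- volumeContour(kernelUD(gaussCloud(500)), 0.95)
  fresh <- gaussCloud(2000)
  expect_equal(mean(pointsInHomeRange(hr, fresh$lon, fresh$lat)), 0.95,
               tolerance = 0.032)
})

test_that("contours are translation-equivariant within one cell", {
  set.seed(46)
  pts <- gaussCloud(300)
  hr1 <- volumeContour(kernelUD(pts$lon, pts$lat, h = 400), 0.95)
  hr2 <- volumeContour(kernelUD(pts$lon, pts$lat + 0.1, h = 400), 0.95)
  expect_equal(hrArea(hr1), hrArea(hr2), tolerance = 0.02)
  c1 <- hrCentroid(hr1); c2 <- hrCentroid(hr2)
  shift <- haversineM(c1["lon"], c1["lat"] + 0.1, c2["lon"], c2["lat"])
  expect_lt(shift, 2 * hr1@cellSize)
})

test_that("Epanechnikov and Gaussian kernels agree at moderate sample size", {
  set.seed(47)
  pts <- gaussCloud(250, sd_m = 800)
  a1 <- hrArea(volumeContour(kernelUD(pts$lon, pts$lat,
                                      kernel = "epanechnikov"), 0.95))
  a2 <- hrArea(volumeContour(kernelUD(pts$lon, pts$lat,
                                      kernel = "bivnorm"), 0.95))
  expect_lt(abs(a1 - a2) / a2, 0.25)
})

test_that("monthly splits exclude partially tracked months", {
  # deployed 13 June, died 17 January: both edge months drop out
  set.seed(48)
  trk <- clusterTracks(8.68, 50.58, "2019-06-13", 219)  # to 17 Jan 2020
  ms <- monthlySplit(trk)
  expect_true("2019-06" %in% ms$excluded)
  expect_true("2020-01" %in% ms$excluded)
  expect_true(all(c("2019-07", "2019-12") %in% names(ms$months)))
  expect_equal(length(ms$months), 6)  # Jul-Dec
  # tolerance: a track starting on the 2nd still spans the month
  trk2 <- clusterTracks(8.68, 50.58, "2019-06-02", 60)
  expect_true("2019-06" %in% names(monthlySplit(trk2)$months))
})

test_that("habitat composition fractions are exact on constructed rasters", {
  # a home range wholly inside urban fabric
  g <- simulateLandcover(c(8, 9.4, 50, 51.2), 0.01, c(8.7, 50.6), 30,
                         agri_outer_km = 45, green_frac = 0.01)
  set.seed(49)
  pts <- gaussCloud(200, sd_m = 1500, lon0 = 8.7, lat0 = 50.6)
  hr <- volumeContour(kernelUD(pts$lon, pts$lat), 0.95)
  hc <- habitatComposition(hr, g)
  expect_equal(sum(hc$classes$fraction), 1, tolerance = 1e-6)
  expect_equal(hc$classes$fraction[hc$classes$code == 112], 1)
  # a cloud straddling the straight north-south class boundary of a
  # two-class raster splits 50/50 up to cell quantization
  vals <- matrix(rep(c(211, 112), each = 50), 100, 100, byrow = TRUE)
  g2 <- asciiGrid(vals, 8, 50, 0.01)  # west half 112? rows are N-S: top=211
  pts2 <- data.frame(lon = runif(400, 8.3, 8.7), lat = runif(400, 50.3, 50.7))
  hr2 <- volumeContour(kernelUD(pts2$lon, pts2$lat, h = 3000), 0.95)
  hc2 <- habitatComposition(hr2, g2)
  expect_equal(hc2$classes$fraction[hc2$classes$code == 211], 0.5,
               tolerance = 0.05)
  expect_equal(sum(hc2$level1$fraction), 1, tolerance = 1e-6)
  # a contour beyond the raster is an error naming the gap
  gSmall <- asciiGrid(matrix(112, 5, 5), 8.69, 50.59, 0.001)
  expect_error(habitatComposition(hr, gSmall), "beyond the land-cover raster")
})
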