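# Shared fixture builders; all synthetic, constructed in code.

makeTracks <- function(lon, lat, times, id = "b1", source = "gps",
                       lc = NA_character_) {
  data.frame(individual_id = id,
             timestamp = as.POSIXct(times, tz = "UTC"),
             lon = lon, lat = lat, source = source, lc = lc,
             stringsAsFactors = FALSE)
}

# n fixes per day at the given lon/lat over consecutive days
clusterTracks <- function(lon, lat, start, days, per_day = 4, id = "b1",
                          jitter_deg = 0.001) {
  t0 <- as.POSIXct(paste(start, "06:00:00"), tz = "UTC")
  times <- rep(seq(0, days - 1) * 86400, each = per_day) +
    rep(seq(0, per_day - 1) * 3600 * 3, days)
  n <- length(times)
  makeTracks(lon + stats::runif(n, -jitter_deg, jitter_deg),
             lat + stats::runif(n, -jitter_deg, jitter_deg),
             t0 + times, id = id)
}

# uniform UD over the first k cells of an nx-by-nx grid (row-major ties)
uniformUD <- function(k, nx = 10, cellSize = 100) {
  dens <- matrix(0, nx, nx)
  v <- 1 / (k * cellSize^2)
  dens[seq_len(k)] <- v
  methods::new("UDSurface", density = dens, xmin = 0, ymin = 0,
               cellSize = cellSize, kernel = "epanechnikov", h = 50,
               nPoints = 10L, lon0 = 8, lat0 = 50)
}

# isotropic Gaussian cloud (sd_m) around a lon/lat centre
gaussCloud <- function(n, sd_m = 1000, lon0 = 8.68, lat0 = 50.58) {
  xy <- cbind(stats::rnorm(n, 0, sd_m), stats::rnorm(n, 0, sd_m))
  ll <- unprojectAEQ(xy[, 1], xy[, 2], lon0, lat0)
  data.frame(lon = ll[, "lon"], lat = ll[, "lat"])
}
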