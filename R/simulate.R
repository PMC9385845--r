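# Individual-based simulator of partial-migrant annual cycles. The movement
# model is deliberately simple -- discrete daily waypoints with within-day
# (great-circle) linear interpolation -- but it carries exact ground truth:
# phase boundaries, site centres, stopovers and foraging trips are all
# recorded, so every downstream rule can be tested against known answers.

M_PER_DEG <- pi * 6378137 / 180

# sample() that never unfolds a scalar into 1:x
.resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best & Fisher (1979) rejection sampler; for `kappa` near zero falls back
#' to the circular uniform. Used for concentrated foraging-trip directions.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees within `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * .rad2deg(acos(f))) %% 360
      i <- i + 1L
    }
  }
  out
}

# 2D Gaussian positional error truncated radially at 3 sd, so every observed
# fix is within 3 error-sd of the true position by construction.
.posError <- function(n, sd_m) {
  u <- stats::runif(n)
  r <- sd_m * sqrt(-2 * log(1 - u * (1 - exp(-4.5))))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(dx = r * cos(th), dy = r * sin(th))
}

.offsetLonLat <- function(lon, lat, dx_m, dy_m) {
  cbind(lon = lon + dx_m / (M_PER_DEG * cos(.deg2rad(lat))),
        lat = lat + dy_m / M_PER_DEG)
}

#' Simulation configuration for the annual-cycle track generator
#'
#' Defaults describe a central-European urban woodpigeon population: breeding
#' around a city at (8.68 E, 50.58 N), facultative migration (probability
#' 0.4 per winter) to scattered wintering sites in south-western France,
#' daily out-and-back foraging commutes of 5.7 +/- 2.0 km with a
#' concentrated south-westerly direction, migration legs of 110-160 km/day
#' interrupted by 1-3 stopovers of 3-4 days, a daylight-only GPS schedule and
#' an Argos duty cycle of 10 h ON / 48 h OFF with location-class-dependent
#' positional error (250/500/1500 m for LC 3/2/1).
#'
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   output.
#' @param n_individuals Number of birds.
#' @param start Simulation start date (breeding season; ISO string or Date).
#' @param n_days Length of the simulated period in days.
#' @param breeding_center `c(lon, lat)` of the breeding population centre.
#' @param breeding_radius_km Radius within which individual breeding sites
#'   (and the residency random walk) are confined.
#' @param p_migrate_per_winter Probability that an individual migrates in a
#'   given winter (strategy is redrawn each year: facultative partial
#'   migration).
#' @param winter_center `c(lon, lat)` of the wintering quarter.
#' @param winter_spread_km Among-individual scatter (sd, km) of main
#'   wintering sites around `winter_center`.
#' @param n_winter_sites_range Integer range of distinct wintering sites
#'   per migrant winter (1-3).
#' @param winter_site_shift_km Range (km) of within-winter site shifts.
#' @param leg_length_km_per_day Range (km) of daily migration legs.
#' @param stopover_count_range Integer range of stopovers per migration leg.
#' @param stopover_days_range Integer range of stopover durations (days).
#' @param stopover_min_days Minimum stopover duration the generator will
#'   produce (>= 1; analysis default is 3 days).
#' @param autumn_depart_doy,spring_depart_doy `c(mean, sd)` of departure
#'   day-of-year for autumn and spring migration.
#' @param foraging_trip_prob_per_day Probability of a foraging commute on a
#'   stationary breeding-site day.
#' @param foraging_distance_km `c(mean, sd)` of commute distance (km).
#' @param foraging_direction_deg `c(mean direction, von Mises kappa)`.
#' @param residency_walk_km Daily sd (km) of the within-site random walk.
#' @param gps_interval_min GPS fix interval in minutes.
#' @param gps_day_window Local-hour pair for the daylight GPS window.
#' @param gps_error_m GPS positional error sd (m).
#' @param argos_interval_min Fix interval while the Argos duty cycle is ON.
#' @param argos_duty_on_h,argos_duty_off_h Argos duty cycle (hours).
#' @param argos_lc_error_m Named map from location class to error sd (m).
#' @param argos_lc_probs Named sampling weights of the location classes.
#' @param outlier_rate Fraction of fixes displaced so that their implied
#'   speed exceeds the 30 m/s ceiling.
#' @param outlier_displacement_km Minimum displacement of an outlier fix.
#' @param source `"gps"` or `"argos"` observation model.
#' @return A validated list of class `simConfig`.
#' @seealso [simulateTracks()]
#' @export
simConfig <- function(seed = 1L,
                      n_individuals = 10L,
                      start = "2019-04-01",
                      n_days = 420L,
                      breeding_center = c(8.68, 50.58),
                      breeding_radius_km = 5,
                      p_migrate_per_winter = 0.4,
                      winter_center = c(0.5, 44.3),
                      winter_spread_km = 150,
                      n_winter_sites_range = c(1L, 3L),
                      winter_site_shift_km = c(25, 60),
                      leg_length_km_per_day = c(110, 160),
                      stopover_count_range = c(1L, 3L),
                      stopover_days_range = c(3L, 4L),
                      stopover_min_days = 3,
                      autumn_depart_doy = c(295, 8),
                      spring_depart_doy = c(82, 8),
                      foraging_trip_prob_per_day = 0.3,
                      foraging_distance_km = c(5.7, 2.0),
                      foraging_direction_deg = c(225, 4),
                      residency_walk_km = 0.3,
                      gps_interval_min = 60,
                      gps_day_window = c(6, 20),
                      gps_error_m = 10,
                      argos_interval_min = 90,
                      argos_duty_on_h = 10,
                      argos_duty_off_h = 48,
                      argos_lc_error_m = c("3" = 250, "2" = 500, "1" = 1500),
                      argos_lc_probs = c("3" = 0.3, "2" = 0.4, "1" = 0.3),
                      outlier_rate = 0,
                      outlier_displacement_km = 200,
                      source = c("gps", "argos")) {
  source <- match.arg(source)
  cfg <- as.list(environment())
  cfg$start <- as.Date(start)
  cfg$seed <- as.integer(seed)
  cfg$n_days <- as.integer(n_days)
  cfg$n_individuals <- as.integer(n_individuals)
  probs <- c(p_migrate_per_winter, foraging_trip_prob_per_day, outlier_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (breeding_radius_km <= 0 || winter_spread_km < 0 ||
      any(leg_length_km_per_day <= 0) || foraging_distance_km[1] <= 0)
    stop("radii and distances must be positive")
  if (stopover_min_days < 1) stop("stopover_min_days must be >= 1")
  if (any(stopover_days_range < stopover_min_days))
    stop("stopover_days_range below stopover_min_days")
  if (any(n_winter_sites_range < 1L) || any(n_winter_sites_range > 3L))
    stop("n_winter_sites_range must be within 1..3")
  if (p_migrate_per_winter > 0) {
    d <- haversineM(breeding_center[1], breeding_center[2],
                    winter_center[1], winter_center[2]) / 1000
    if (d <= breeding_radius_km)
      stop("configuration error: winter center lies within the breeding radius")
  }
  if (!as.integer(format(cfg$start, "%m")) %in% 3:9)
    stop("simulation must start in the breeding season (March-September)")
  if (abs(sum(argos_lc_probs) - 1) > 1e-8)
    stop("argos_lc_probs must sum to 1")
  if (!all(names(argos_lc_probs) %in% names(argos_lc_error_m)))
    stop("argos_lc_probs classes missing from argos_lc_error_m")
  class(cfg) <- "simConfig"
  cfg
}

# Random point within a disc of radius_km around c(lon, lat).
.randomInDisc <- function(center, radius_km) {
  b <- stats::runif(1, 0, 360)
  d <- radius_km * sqrt(stats::runif(1)) * 1000
  p <- destinationPoint(center[1], center[2], b, d)
  c(p[1, "lon"], p[1, "lat"])
}

# Build the day-by-day plan of one individual plus its truth tables.
# Plan day types: "stationary" (anchored at a site or stopover point),
# "commute" (out-and-back foraging trip), "travel" (migration/shift leg).
.planIndividual <- function(cfg, id) {
  nd <- cfg$n_days
  dates <- cfg$start + seq_len(nd) - 1
  bsite <- .randomInDisc(cfg$breeding_center, cfg$breeding_radius_km)
  sites <- data.frame(site_id = "B", type = "breeding",
                      lon = bsite[1], lat = bsite[2],
                      stringsAsFactors = FALSE)
  plan <- data.frame(date = dates, type = "stationary",
                     slon = NA_real_, slat = NA_real_,
                     elon = NA_real_, elat = NA_real_,
                     tlon = NA_real_, tlat = NA_real_,
                     phase = NA_character_, site_id = NA_character_,
                     stringsAsFactors = FALSE)
  phases <- migrations <- stopovers <- shifts <- NULL

  markStationary <- function(d1, d2, phase, site_id) {
    if (d2 < d1) return(invisible())
    plan$type[d1:d2] <<- "stationary"
    plan$phase[d1:d2] <<- phase
    plan$site_id[d1:d2] <<- site_id
  }
  # Directed migration from `from` to `to` starting on day d0; returns the
  # day index after arrival and the arrival day itself.
  buildMigration <- function(d0, from, to, season) {
    D <- haversineM(from[1], from[2], to[1], to[2]) / 1000
    legs <- numeric()
    rem <- D
    while (rem > 1e-9) {
      lg <- stats::runif(1, cfg$leg_length_km_per_day[1],
                         cfg$leg_length_km_per_day[2])
      if (rem <= lg * 1.3) lg <- rem
      legs <- c(legs, lg)
      rem <- rem - lg
    }
    nTravel <- length(legs)
    nStop <- .resample(cfg$stopover_count_range[1]:cfg$stopover_count_range[2])
    nStop <- min(nStop, max(nTravel - 1, 0))
    stopAfter <- if (nStop > 0) sort(.resample(seq_len(nTravel - 1), nStop)) else integer()
    stopDur <- .resample(cfg$stopover_days_range[1]:cfg$stopover_days_range[2],
                         nStop, replace = TRUE)
    cum <- cumsum(legs) / D
    wp <- rbind(c(from[1], from[2]),
                greatCircleInterp(from[1], from[2], to[1], to[2], cum))
    d <- d0
    for (j in seq_len(nTravel)) {
      if (d > nd) break
      plan$type[d] <<- "travel"
      plan$slon[d] <<- wp[j, 1]; plan$slat[d] <<- wp[j, 2]
      plan$elon[d] <<- wp[j + 1, 1]; plan$elat[d] <<- wp[j + 1, 2]
      plan$phase[d] <<- season
      d <- d + 1
      k <- match(j, stopAfter)
      if (!is.na(k) && d <= nd) {
        dEnd <- min(d + stopDur[k] - 1, nd)
        plan$type[d:dEnd] <<- "stationary"
        plan$slon[d:dEnd] <<- wp[j + 1, 1]; plan$slat[d:dEnd] <<- wp[j + 1, 2]
        plan$phase[d:dEnd] <<- season
        stopovers <<- rbind(stopovers, data.frame(
          season = season, start_date = dates[d], end_date = dates[dEnd],
          lon = wp[j + 1, 1], lat = wp[j + 1, 2],
          duration_days = as.numeric(dates[dEnd] - dates[d]) + 1,
          stringsAsFactors = FALSE))
        d <- dEnd + 1
      }
    }
    list(next_day = d, arrival_day = min(d - 1, nd))
  }

  d <- 1L
  phaseStart <- 1L
  curPhase <- "breeding"; curSiteId <- "B"; curSite <- bsite
  y <- as.integer(format(cfg$start, "%Y"))
  winterIdx <- 0L
  while (d <= nd) {
    migrate <- stats::runif(1) < cfg$p_migrate_per_winter
    depDoy <- round(stats::rnorm(1, cfg$autumn_depart_doy[1],
                                 cfg$autumn_depart_doy[2]))
    depIdx <- as.integer(as.Date(sprintf("%d-01-01", y)) + depDoy - 1 -
                           cfg$start) + 1L
    if (depIdx < d) depIdx <- d
    if (!migrate || depIdx > nd) {
      # resident this winter (or the period ends first): sit tight until the
      # start of the next decision year
      endStay <- min(nd, as.integer(as.Date(sprintf("%d-03-01", y + 1L)) -
                                      cfg$start))
      if (depIdx > nd) endStay <- nd
      markStationary(d, endStay, curPhase, curSiteId)
      d <- endStay + 1L
      y <- y + 1L
      next
    }
    winterIdx <- winterIdx + 1L
    markStationary(d, depIdx - 1L, curPhase, curSiteId)
    if (depIdx - 1L >= phaseStart)
      phases <- rbind(phases, data.frame(
        phase = curPhase, site_id = curSiteId,
        start_date = dates[phaseStart], end_date = dates[depIdx - 1L],
        site_lon = curSite[1], site_lat = curSite[2], stringsAsFactors = FALSE))
    # wintering sites for this winter
    off <- stats::rnorm(2, 0, cfg$winter_spread_km * 1000)
    w1ll <- unprojectAEQ(off[1], off[2], cfg$winter_center[1], cfg$winter_center[2])
    wSites <- list(c(w1ll[1, "lon"], w1ll[1, "lat"]))
    nW <- .resample(cfg$n_winter_sites_range[1]:cfg$n_winter_sites_range[2])
    if (nW > 1) for (k in 2:nW) {
      prev <- wSites[[k - 1]]
      sh <- stats::runif(1, cfg$winter_site_shift_km[1], cfg$winter_site_shift_km[2])
      p <- destinationPoint(prev[1], prev[2], stats::runif(1, 0, 360), sh * 1000)
      wSites[[k]] <- c(p[1, "lon"], p[1, "lat"])
    }
    mig <- buildMigration(depIdx, curSite, wSites[[1]], "autumn_migration")
    migrations <- rbind(migrations, data.frame(
      season = "autumn_migration", dep_date = dates[depIdx],
      arr_date = dates[mig$arrival_day], from_site = curSiteId,
      to_site = sprintf("W%d.1", winterIdx), stringsAsFactors = FALSE))
    phases <- rbind(phases, data.frame(
      phase = "autumn_migration", site_id = NA_character_,
      start_date = dates[depIdx], end_date = dates[mig$arrival_day],
      site_lon = NA_real_, site_lat = NA_real_, stringsAsFactors = FALSE))
    d <- mig$next_day
    if (d > nd) { phaseStart <- nd + 1L; break }
    # wintering: contiguous occupancy chunks over 1-3 sites
    sprDoy <- round(stats::rnorm(1, cfg$spring_depart_doy[1],
                                 cfg$spring_depart_doy[2]))
    sprIdx <- as.integer(as.Date(sprintf("%d-01-01", y + 1L)) + sprDoy - 1 -
                           cfg$start) + 1L
    if (sprIdx <= d + 7L) sprIdx <- d + 8L
    wEnd <- min(sprIdx - 1L, nd)
    nWdays <- wEnd - d + 1L
    while (nW > 1 && nWdays < nW * 8L) nW <- nW - 1L
    bounds <- d + floor(nWdays * seq(0, nW) / nW)
    for (k in seq_len(nW)) {
      s0 <- as.integer(bounds[k]); s1 <- as.integer(bounds[k + 1]) - 1L
      sid <- sprintf("W%d.%d", winterIdx, k)
      sites <- rbind(sites, data.frame(site_id = sid, type = "wintering",
                                       lon = wSites[[k]][1], lat = wSites[[k]][2],
                                       stringsAsFactors = FALSE))
      if (k > 1) {
        plan$type[s0] <- "travel"
        plan$slon[s0] <- wSites[[k - 1]][1]; plan$slat[s0] <- wSites[[k - 1]][2]
        plan$elon[s0] <- wSites[[k]][1]; plan$elat[s0] <- wSites[[k]][2]
        plan$phase[s0] <- "wintering"
        shifts <- rbind(shifts, data.frame(
          date = dates[s0], from_site = sprintf("W%d.%d", winterIdx, k - 1L),
          to_site = sid, stringsAsFactors = FALSE))
        markStationary(min(s0 + 1L, s1), s1, "wintering", sid)
        if (s0 + 1L > s1) plan$site_id[s0] <- sid
      } else {
        markStationary(s0, s1, "wintering", sid)
      }
      phases <- rbind(phases, data.frame(
        phase = "wintering", site_id = sid,
        start_date = dates[s0], end_date = dates[s1],
        site_lon = wSites[[k]][1], site_lat = wSites[[k]][2],
        stringsAsFactors = FALSE))
    }
    d <- wEnd + 1L
    if (d > nd) { phaseStart <- nd + 1L; break }
    mig <- buildMigration(d, wSites[[nW]], bsite, "spring_migration")
    migrations <- rbind(migrations, data.frame(
      season = "spring_migration", dep_date = dates[d],
      arr_date = dates[mig$arrival_day],
      from_site = sprintf("W%d.%d", winterIdx, nW), to_site = "B",
      stringsAsFactors = FALSE))
    phases <- rbind(phases, data.frame(
      phase = "spring_migration", site_id = NA_character_,
      start_date = dates[d], end_date = dates[mig$arrival_day],
      site_lon = NA_real_, site_lat = NA_real_, stringsAsFactors = FALSE))
    d <- mig$next_day
    curPhase <- "breeding"; curSiteId <- "B"; curSite <- bsite
    phaseStart <- d
    y <- y + 1L
  }
  if (phaseStart <= nd) {
    markStationary(phaseStart, nd, curPhase, curSiteId)
    phases <- rbind(phases, data.frame(
      phase = curPhase, site_id = curSiteId,
      start_date = dates[phaseStart], end_date = dates[nd],
      site_lon = curSite[1], site_lat = curSite[2], stringsAsFactors = FALSE))
  }

  # fill stationary-day anchors (residency random walk, clamped) and draw
  # foraging commutes from the breeding site
  walk <- c(0, 0)
  foraging <- NULL
  rmax <- cfg$breeding_radius_km * 1000 * 0.8
  for (i in seq_len(nd)) {
    if (plan$type[i] == "travel") { walk <- c(0, 0); next }
    sid <- plan$site_id[i]
    anchor <- if (!is.na(sid)) {
      si <- match(sid, sites$site_id)
      c(sites$lon[si], sites$lat[si])
    } else c(plan$slon[i], plan$slat[i])
    step <- stats::rnorm(2, 0, cfg$residency_walk_km * 1000)
    walk <- walk + step
    r <- sqrt(sum(walk^2))
    if (r > rmax) walk <- walk * rmax / r
    pos <- .offsetLonLat(anchor[1], anchor[2], walk[1], walk[2])
    plan$slon[i] <- pos[1, "lon"]; plan$slat[i] <- pos[1, "lat"]
    plan$elon[i] <- pos[1, "lon"]; plan$elat[i] <- pos[1, "lat"]
    if (identical(sid, "B") &&
        stats::runif(1) < cfg$foraging_trip_prob_per_day) {
      dist <- max(0.5, stats::rnorm(1, cfg$foraging_distance_km[1],
                                    cfg$foraging_distance_km[2]))
      bear <- rvonmises(1, cfg$foraging_direction_deg[1],
                        cfg$foraging_direction_deg[2])
      tgt <- destinationPoint(pos[1, "lon"], pos[1, "lat"], bear, dist * 1000)
      plan$type[i] <- "commute"
      plan$tlon[i] <- tgt[1, "lon"]; plan$tlat[i] <- tgt[1, "lat"]
      foraging <- rbind(foraging, data.frame(
        date = dates[i], target_lon = tgt[1, "lon"], target_lat = tgt[1, "lat"],
        distance_km = dist, bearing_deg = bear, stringsAsFactors = FALSE))
    }
  }
  list(individual_id = id, plan = plan, sites = sites, phases = phases,
       migrations = migrations, stopovers = stopovers, shifts = shifts,
       foraging = foraging)
}

# True position of one planned day at fractional hours h (vector).
.dayPositions <- function(row, h) {
  if (row$type == "stationary") {
    return(cbind(lon = rep(row$slon, length(h)), lat = rep(row$slat, length(h))))
  }
  if (row$type == "travel") {
    f <- pmin(1, pmax(0, (h - 8) / 10))  # travel 08:00-18:00
    return(greatCircleInterp(row$slon, row$slat, row$elon, row$elat, f))
  }
  # commute: out 09:00-12:00, at target 12:00-14:00, back 14:00-17:00
  f <- numeric(length(h))
  out1 <- h >= 9 & h < 12
  there <- h >= 12 & h < 14
  back <- h >= 14 & h < 17
  f[out1] <- (h[out1] - 9) / 3
  f[there] <- 1
  f[back] <- (17 - h[back]) / 3
  greatCircleInterp(row$slon, row$slat, row$tlon, row$tlat, f)
}

#' Simulate tracking data with ground truth
#'
#' Runs the annual-cycle movement model for each configured individual and
#' samples it through the configured observation model (daylight GPS schedule
#' or Argos duty cycle with location-class errors). A fraction
#' `outlier_rate` of fixes is displaced far enough that the implied speed
#' from the previous fix exceeds the 30 m/s flight ceiling, for exercising
#' the speed filter.
#'
#' @param config A [simConfig()].
#' @return `list(locations =, truth =)`. `locations` is a data.frame with the
#'   documented track columns plus `true_lon`, `true_lat` and `outlier`
#'   (dropped by [writeTracksCSV()]); `truth` is a list of per-individual
#'   records with elements `plan`, `sites`, `phases`, `migrations`,
#'   `stopovers`, `shifts` and `foraging`.
#' @examples
#' sim <- simulateTracks(simConfig(seed = 1, n_individuals = 2, n_days = 90))
#' head(sim$locations)
#' @export
simulateTracks <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(config$seed, {
    truths <- list()
    locs <- vector("list", config$n_individuals)
    for (i in seq_len(config$n_individuals)) {
      id <- sprintf("bird%02d", i)
      tr <- .planIndividual(config, id)
      truths[[id]] <- tr
      locs[[i]] <- .observeIndividual(config, tr)
    }
    locations <- do.call(rbind, locs)
    rownames(locations) <- NULL
    list(locations = locations, truth = truths)
  })
}

.observeIndividual <- function(cfg, tr) {
  nd <- cfg$n_days
  plan <- tr$plan
  if (cfg$source == "gps") {
    hours <- seq(cfg$gps_day_window[1], cfg$gps_day_window[2],
                 by = cfg$gps_interval_min / 60)
    dayHours <- rep(list(hours), nd)
  } else {
    period <- cfg$argos_duty_on_h + cfg$argos_duty_off_h
    allH <- seq(0, nd * 24 - 1e-9, by = cfg$argos_interval_min / 60)
    allH <- allH[(allH %% period) < cfg$argos_duty_on_h]
    dayIdx <- floor(allH / 24) + 1
    dayHours <- split(allH %% 24, factor(dayIdx, levels = seq_len(nd)))
  }
  out <- vector("list", nd)
  for (d in seq_len(nd)) {
    h <- dayHours[[d]]
    if (!length(h)) next
    pos <- .dayPositions(plan[d, ], h)
    out[[d]] <- data.frame(day = d, hour = h,
                           true_lon = pos[, "lon"], true_lat = pos[, "lat"])
  }
  df <- do.call(rbind, out)
  n <- nrow(df)
  ts <- as.POSIXct(as.numeric(as.POSIXct(paste(cfg$start), tz = "UTC")) +
                     ((df$day - 1) * 24 + df$hour) * 3600,
                   origin = "1970-01-01", tz = "UTC")
  if (cfg$source == "gps") {
    lc <- rep(NA_character_, n)
    sd_m <- rep(cfg$gps_error_m, n)
  } else {
    lc <- sample(names(cfg$argos_lc_probs), n, replace = TRUE,
                 prob = cfg$argos_lc_probs)
    sd_m <- unname(cfg$argos_lc_error_m[lc])
  }
  err <- .posError(n, 1)
  ll <- .offsetLonLat(df$true_lon, df$true_lat,
                      err[, "dx"] * sd_m, err[, "dy"] * sd_m)
  res <- data.frame(individual_id = tr$individual_id, timestamp = ts,
                    lon = ll[, "lon"], lat = ll[, "lat"],
                    source = cfg$source, lc = lc,
                    true_lon = df$true_lon, true_lat = df$true_lat,
                    outlier = FALSE, stringsAsFactors = FALSE)
  if (cfg$outlier_rate > 0 && n > 2) {
    nOut <- round(cfg$outlier_rate * n)
    if (nOut > 0) {
      idx <- sort(sample(2:n, min(nOut, n - 1)))
      dt <- as.numeric(difftime(res$timestamp[idx], res$timestamp[idx - 1],
                                units = "secs"))
      dispKm <- pmax(cfg$outlier_displacement_km, 0.045 * dt)
      bear <- stats::runif(length(idx), 0, 360)
      p <- destinationPoint(res$lon[idx], res$lat[idx], bear, dispKm * 1000)
      res$lon[idx] <- p[, "lon"]; res$lat[idx] <- p[, "lat"]
      res$outlier[idx] <- TRUE
    }
  }
  res
}
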