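# Segmentation of filtered tracks into breeding / migration / stopover /
# wintering phases, and midpoint-rule migration phenology. The quantitative
# rules: a migration opens at the first fix at least 100 km from the current
# stationary site; a stopover is a spatially overlapping run of at least 3
# days inside a migration; phase-boundary dates are the calendar midpoint of
# the flanking signals, excluded when the transmission gap exceeds 14 days.

#' Detect stationary location runs and candidate sites
#'
#' Greedy forward pass per individual: a run grows while each new fix stays
#' within `radius_km` of the running centroid of the run. Runs whose time
#' span reaches `min_days` are breeding/wintering site candidates
#' (`is_site`); shorter runs are kept because migration stopovers are found
#' among them.
#'
#' @param tracks Filtered, time-sorted location data.frame.
#' @param radius_km Spatial-overlap radius (km); default 20.
#' @param min_days Minimum span (days) for site candidacy; default 5.
#' @return data.frame of runs: `individual_id`, `run`, `first_signal`,
#'   `last_signal`, `center_lon`, `center_lat`, `n_fixes`, `span_days`,
#'   `is_site`, plus `first_idx`/`last_idx` into the individual's fixes.
#' @export
detectStationarySites <- function(tracks, radius_km = 20, min_days = 5) {
  if (!nrow(tracks)) {
    return(data.frame(individual_id = character(), run = integer(),
                      first_signal = as.POSIXct(character(), tz = "UTC"),
                      last_signal = as.POSIXct(character(), tz = "UTC"),
                      center_lon = numeric(), center_lat = numeric(),
                      n_fixes = integer(), span_days = numeric(),
                      is_site = logical()))
  }
  out <- NULL
  for (id in unique(tracks$individual_id)) {
    sub <- tracks[tracks$individual_id == id, , drop = FALSE]
    n <- nrow(sub)
    runStart <- 1L
    cx <- sub$lon[1]; cy <- sub$lat[1]
    k <- 1L
    runId <- 0L
    closeRun <- function(i0, i1, cx, cy) {
      span <- as.numeric(difftime(sub$timestamp[i1], sub$timestamp[i0],
                                  units = "days"))
      data.frame(individual_id = id, run = runId,
                 first_signal = sub$timestamp[i0],
                 last_signal = sub$timestamp[i1],
                 center_lon = cx, center_lat = cy,
                 n_fixes = i1 - i0 + 1L, span_days = span,
                 is_site = span >= min_days,
                 first_idx = i0, last_idx = i1,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(n)[-1]) {
      d <- haversineM(cx, cy, sub$lon[i], sub$lat[i]) / 1000
      if (d <= radius_km) {
        cx <- (cx * k + sub$lon[i]) / (k + 1)
        cy <- (cy * k + sub$lat[i]) / (k + 1)
        k <- k + 1L
      } else {
        runId <- runId + 1L
        out <- rbind(out, closeRun(runStart, i - 1L, cx, cy))
        runStart <- i
        cx <- sub$lon[i]; cy <- sub$lat[i]
        k <- 1L
      }
    }
    runId <- runId + 1L
    out <- rbind(out, closeRun(runStart, n, cx, cy))
  }
  rownames(out) <- NULL
  out
}

# Cluster site-run centres: same site when within radius_km of an existing
# site centre (greedy, in temporal order).
.clusterSites <- function(runs, radius_km) {
  centers <- NULL
  ids <- integer(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    if (is.null(centers)) {
      centers <- data.frame(lon = runs$center_lon[i], lat = runs$center_lat[i])
      ids[i] <- 1L
      next
    }
    d <- haversineM(centers$lon, centers$lat,
                    runs$center_lon[i], runs$center_lat[i]) / 1000
    j <- which(d <= radius_km)
    if (length(j)) {
      ids[i] <- j[1]
    } else {
      centers <- rbind(centers, data.frame(lon = runs$center_lon[i],
                                           lat = runs$center_lat[i]))
      ids[i] <- nrow(centers)
    }
  }
  list(ids = ids, centers = centers)
}

#' Segment a track into annual-cycle phases
#'
#' Stationary site occupancies come from [detectStationarySites()]; the
#' breeding site is the site holding the most fixes in April-August.
#' Transitions between consecutive site occupancies at least
#' `min_migration_km` apart become migration intervals: the migration opens
#' at the first fix at least `min_migration_km` from the previous site
#' centre and closes at the last fix before the next occupancy begins.
#' Distinct-site movements shorter than `min_migration_km` are recorded as
#' site shifts (wintering-site changes), not migration. Stationary runs of
#' at least `stopover_min_days` inside a migration interval are stopovers.
#' A track that ends (or begins) in mid-migration yields an interval with
#' `complete = FALSE`.
#'
#' @param tracks Filtered location data.frame (one or more individuals).
#' @param min_migration_km Displacement defining migration onset (100 km).
#' @param stopover_min_days Minimum stopover duration in days (3).
#' @param site_radius_km Spatial-overlap radius for runs and site identity.
#' @param site_min_days Minimum span for breeding/wintering site candidacy.
#' @return `list(phases =, stopovers =, shifts =)`; `phases` has one row per
#'   phase interval with `individual_id`, `phase`, `site_id`, `first_signal`,
#'   `last_signal`, `site_lon`, `site_lat`, `complete`.
#' @export
segmentAnnualCycle <- function(tracks, min_migration_km = 100,
                               stopover_min_days = 3,
                               site_radius_km = 20, site_min_days = 5) {
  stopifnot(min_migration_km > 0, stopover_min_days >= 1)
  phases <- stopovers <- shifts <- NULL
  for (id in unique(tracks$individual_id)) {
    sub <- tracks[tracks$individual_id == id, , drop = FALSE]
    runs <- detectStationarySites(sub, site_radius_km, site_min_days)
    siteRuns <- runs[runs$is_site, , drop = FALSE]
    if (!nrow(siteRuns)) next
    cl <- .clusterSites(siteRuns, site_radius_km)
    siteRuns$site <- cl$ids
    # merge consecutive occupancies of the same site into episodes
    ep <- siteRuns[1, , drop = FALSE]
    if (nrow(siteRuns) > 1) {
      keep <- list(ep)
      for (i in 2:nrow(siteRuns)) {
        last <- keep[[length(keep)]]
        if (siteRuns$site[i] == last$site[nrow(last)]) {
          last$last_signal[nrow(last)] <- siteRuns$last_signal[i]
          last$last_idx[nrow(last)] <- siteRuns$last_idx[i]
          last$n_fixes[nrow(last)] <- last$n_fixes[nrow(last)] + siteRuns$n_fixes[i]
          keep[[length(keep)]] <- last
        } else {
          keep[[length(keep) + 1]] <- siteRuns[i, , drop = FALSE]
        }
      }
      ep <- do.call(rbind, keep)
    }
    # breeding site = site with most fixes in Apr-Aug
    mon <- as.integer(format(sub$timestamp, "%m", tz = "UTC"))
    siteFixCount <- sapply(seq_len(nrow(cl$centers)), function(s) {
      idx <- unlist(lapply(which(ep$site == s), function(e)
        seq(ep$first_idx[e], ep$last_idx[e])))
      sum(mon[idx] %in% 4:8)
    })
    breedingSite <- which.max(siteFixCount)
    ep$phase <- ifelse(
      ep$site == breedingSite, "breeding",
      ifelse(haversineM(cl$centers$lon[ep$site], cl$centers$lat[ep$site],
                        cl$centers$lon[breedingSite],
                        cl$centers$lat[breedingSite]) / 1000 >= min_migration_km |
               as.integer(format(ep$first_signal, "%m", tz = "UTC")) %in% c(10:12, 1:3),
             "wintering", "breeding")
    )
    addPhase <- function(phase, site, i0, i1, complete = TRUE) {
      lonlat <- if (is.na(site)) c(NA_real_, NA_real_) else
        c(cl$centers$lon[site], cl$centers$lat[site])
      data.frame(individual_id = id, phase = phase,
                 site_id = if (is.na(site)) NA_character_ else
                   sprintf("S%d", site),
                 first_signal = sub$timestamp[i0], last_signal = sub$timestamp[i1],
                 site_lon = lonlat[1], site_lat = lonlat[2],
                 complete = complete, stringsAsFactors = FALSE)
    }
    for (e in seq_len(nrow(ep))) {
      phases <- rbind(phases, addPhase(ep$phase[e], ep$site[e],
                                       ep$first_idx[e], ep$last_idx[e]))
      if (e == nrow(ep)) {
        # trailing fixes after the last occupancy: possible open migration
        i0 <- ep$last_idx[e] + 1L
        if (i0 <= nrow(sub)) {
          dd <- haversineM(cl$centers$lon[ep$site[e]], cl$centers$lat[ep$site[e]],
                           sub$lon[i0:nrow(sub)], sub$lat[i0:nrow(sub)]) / 1000
          hit <- which(dd >= min_migration_km)
          if (length(hit)) {
            j0 <- i0 + hit[1] - 1L
            season <- .migrationSeason(sub$timestamp[j0])
            phases <- rbind(phases, addPhase(season, NA, j0, nrow(sub),
                                             complete = FALSE))
          }
        }
        break
      }
      # transition to next episode
      A <- ep[e, ]; B <- ep[e + 1, ]
      d <- haversineM(cl$centers$lon[A$site], cl$centers$lat[A$site],
                      cl$centers$lon[B$site], cl$centers$lat[B$site]) / 1000
      if (d >= min_migration_km) {
        mid <- seq(A$last_idx + 1L, B$first_idx - 1L)
        mid <- mid[mid >= 1 & mid <= nrow(sub)]
        dA <- if (length(mid))
          haversineM(cl$centers$lon[A$site], cl$centers$lat[A$site],
                     sub$lon[mid], sub$lat[mid]) / 1000 else numeric()
        hit <- which(dA >= min_migration_km)
        if (length(hit)) {
          j0 <- mid[hit[1]]
          j1 <- B$first_idx - 1L
          season <- .migrationSeason(sub$timestamp[j0])
          phases <- rbind(phases, addPhase(season, NA, j0, j1))
          # stopovers: runs inside [j0, j1] spanning >= stopover_min_days
          inRuns <- runs[runs$first_idx >= j0 & runs$last_idx <= j1 &
                           runs$span_days >= stopover_min_days, , drop = FALSE]
          if (nrow(inRuns))
            stopovers <- rbind(stopovers, data.frame(
              individual_id = id, season = season,
              first_signal = inRuns$first_signal,
              last_signal = inRuns$last_signal,
              center_lon = inRuns$center_lon, center_lat = inRuns$center_lat,
              duration_days = inRuns$span_days, stringsAsFactors = FALSE))
        }
      } else {
        shifts <- rbind(shifts, data.frame(
          individual_id = id,
          from_site = sprintf("S%d", A$site), to_site = sprintf("S%d", B$site),
          last_signal_from = A$last_signal, first_signal_to = B$first_signal,
          distance_km = d, stringsAsFactors = FALSE))
      }
    }
  }
  list(phases = phases, stopovers = stopovers, shifts = shifts)
}

.migrationSeason <- function(ts) {
  m <- as.integer(format(ts, "%m", tz = "UTC"))
  if (m %in% c(8:12, 1)) "autumn_migration" else "spring_migration"
}

#' Midpoint phase-boundary date with the 14-day gap rule
#'
#' The boundary between two adjacent annual-cycle phases is taken as the
#' calendar midpoint of the last signal before and the first signal after
#' the transition ("the mean was selected"); if the transmission gap exceeds
#' `max_gap_days` the boundary is excluded (`NA`).
#'
#' @param last_prev,first_next Dates (or POSIXct) flanking the transition.
#' @param max_gap_days Gap above which the boundary is excluded (14).
#' @return Fractional date as numeric days since 1970-01-01 (`NA` if
#'   excluded). Format with [formatFracDate()].
#' @examples
#' formatFracDate(boundaryDate(as.Date("2011-03-16"), as.Date("2011-03-18")))
#' @export
boundaryDate <- function(last_prev, first_next, max_gap_days = 14) {
  a <- as.numeric(as.Date(last_prev))
  b <- as.numeric(as.Date(first_next))
  if (any(is.na(a) | is.na(b))) return(rep(NA_real_, max(length(a), length(b))))
  if (any(b < a)) stop("first_next precedes last_prev")
  out <- (a + b) / 2
  out[b - a > max_gap_days] <- NA_real_
  out
}

#' Format a fractional date
#'
#' @param x Numeric fractional days since 1970-01-01 (see [boundaryDate()]).
#' @return Character like `"2009-03-14.5"`.
#' @export
formatFracDate <- function(x) {
  fl <- floor(x)
  frac <- x - fl
  ifelse(is.na(x), NA_character_,
         paste0(format(as.Date(fl, origin = "1970-01-01")),
                ifelse(frac > 0, sprintf(".%g", frac * 10), "")))
}

#' Common-scale day of year (non-leap reference)
#'
#' Maps a (possibly fractional) date to a day-of-year position on a common
#' 365-day scale so that dates from leap and non-leap years can be averaged:
#' Feb 29 maps to 59.5, Mar 1 is always 60. Used by [phenologySummary()].
#'
#' @param x Dates, or numeric fractional days since 1970-01-01.
#' @return Numeric day-of-year values (1 = Jan 1).
#' @export
doy365 <- function(x) {
  num <- if (inherits(x, "Date")) as.numeric(x) else as.numeric(x)
  fl <- floor(num)
  frac <- num - fl
  d <- as.Date(fl, origin = "1970-01-01")
  mon <- as.integer(format(d, "%m"))
  mday <- as.integer(format(d, "%d"))
  cum <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  doy <- cum[mon] + mday
  doy[mon == 2 & mday == 29] <- 59.5
  doy + frac
}

# inverse of doy365 on the non-leap reference; integer doy in 1..365
.doy365ToLabel <- function(doy) {
  format(as.Date("2001-01-01") + doy - 1, "%d %B")
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Migration phenology across individuals
#'
#' For each individual the event date is the [boundaryDate()] midpoint of
#' the two signals flanking the transition (departure: last signal at the
#' stationary site and first signal of the migration; arrival: last signal
#' of the migration and first at the next site). Events with a transmission
#' gap above `max_gap_days` are excluded. The mean across individuals is
#' computed on the common non-leap day-of-year scale ([doy365()]) and
#' rounded to the nearest whole day (0.5 rounds up) for reporting. Ranges
#' are reported twice, from the stationary-side raw signals and from the
#' migration-side raw signals, because printed ranges in the literature
#' follow raw signals while means follow midpoints.
#'
#' @param phases Phase-interval data.frame (see [segmentAnnualCycle()] or
#'   [woodpigeonPhases()]): columns `individual_id`, `phase`,
#'   `first_signal`, `last_signal`, rows in temporal order per individual.
#' @param event One of `"autumn_departure"`, `"autumn_arrival"`,
#'   `"spring_departure"`, `"spring_arrival"`.
#' @param which_event `"first"` (default) uses each individual's first such
#'   transition, `"all"` pools every transition.
#' @param max_gap_days Exclusion threshold for transmission gaps (14).
#' @return An object of class `phenologySummary`: list with `event`, `n`,
#'   `n_excluded`, `mean_doy`, `mean_date` (label), `events` (per-individual
#'   table), `range_stationary`, `range_migration`.
#' @export
phenologySummary <- function(phases, event = c("autumn_departure",
                                               "autumn_arrival",
                                               "spring_departure",
                                               "spring_arrival"),
                             which_event = c("first", "all"),
                             max_gap_days = 14) {
  event <- match.arg(event)
  which_event <- match.arg(which_event)
  mig <- if (grepl("^autumn", event)) "autumn_migration" else "spring_migration"
  departure <- grepl("departure$", event)
  evs <- NULL
  for (id in unique(phases$individual_id)) {
    sub <- phases[phases$individual_id == id, , drop = FALSE]
    rows <- which(sub$phase == mig)
    for (r in rows) {
      if (departure) {
        if (r == 1) next
        stat <- as.Date(sub$last_signal[r - 1])
        migs <- as.Date(sub$first_signal[r])
      } else {
        if (r == nrow(sub)) next
        stat <- as.Date(sub$first_signal[r + 1])
        migs <- as.Date(sub$last_signal[r])
      }
      if (is.na(stat) || is.na(migs)) next
      bd <- if (departure) boundaryDate(stat, migs, max_gap_days) else
        boundaryDate(migs, stat, max_gap_days)
      evs <- rbind(evs, data.frame(
        individual_id = id, stationary_signal = stat, migration_signal = migs,
        gap_days = abs(as.numeric(stat - migs)),
        midpoint = bd, excluded = is.na(bd), stringsAsFactors = FALSE))
    }
  }
  if (is.null(evs)) {
    out <- list(event = event, n = 0L, n_excluded = 0L, mean_doy = NA_real_,
                mean_date = NA_character_, events = NULL,
                range_stationary = NULL, range_migration = NULL)
    class(out) <- "phenologySummary"
    return(out)
  }
  if (which_event == "first")
    evs <- evs[!duplicated(evs$individual_id), , drop = FALSE]
  kept <- evs[!evs$excluded, , drop = FALSE]
  if (!nrow(kept)) {
    out <- list(event = event, n = 0L, n_excluded = sum(evs$excluded),
                mean_doy = NA_real_, mean_date = NA_character_, events = evs,
                range_stationary = NULL, range_migration = NULL)
    class(out) <- "phenologySummary"
    return(out)
  }
  meanDoy <- .roundHalfUp(mean(doy365(kept$midpoint)))
  out <- list(event = event, n = nrow(kept), n_excluded = sum(evs$excluded),
              mean_doy = meanDoy, mean_date = .doy365ToLabel(meanDoy),
              events = evs,
              range_stationary = range(kept$stationary_signal),
              range_migration = range(kept$migration_signal))
  class(out) <- "phenologySummary"
  out
}

#' @export
print.phenologySummary <- function(x, ...) {
  cat(sprintf("Phenology: %s, n = %d (%d excluded by the gap rule)\n",
              x$event, x$n, x$n_excluded))
  if (!is.na(x$mean_doy))
    cat(sprintf("  mean date: %s (day %g of the non-leap year)\n",
                x$mean_date, x$mean_doy))
  if (!is.null(x$range_stationary))
    cat("  range (stationary-side signals):",
        paste(format(x$range_stationary), collapse = " to "), "\n")
  invisible(x)
}

#' Phase durations (calendar days) with mean and sample sd
#'
#' Duration of each complete interval is `last_signal - first_signal` in
#' calendar days (leap-aware). The sd uses the n-1 denominator and is
#' reported to one decimal; with a single interval the sd is `NA`.
#'
#' @param phases Phase table; only rows with `complete == TRUE` (or with
#'   both signals present when no `complete` column exists) are used.
#' @param phase Phase label to summarise (e.g. `"autumn_migration"`).
#' @return list with `n`, `durations`, `mean`, `sd` (rounded to 1 decimal).
#' @export
phenologyDurations <- function(phases, phase) {
  sub <- phases[phases$phase == phase, , drop = FALSE]
  if ("complete" %in% names(phases)) sub <- sub[sub$complete %in% TRUE, , drop = FALSE]
  a <- as.Date(sub$first_signal); b <- as.Date(sub$last_signal)
  ok <- !is.na(a) & !is.na(b)
  dur <- as.numeric(b[ok] - a[ok])
  list(n = length(dur), durations = dur,
       mean = round(mean(dur), 1),
       sd = if (length(dur) > 1) round(stats::sd(dur), 1) else NA_real_)
}

#' Wintering-site inventory per individual and winter
#'
#' Assigns wintering phase intervals to winter seasons (a winter spans the
#' year boundary and is labelled e.g. `"2019/20"`; intervals starting
#' August-December belong to the winter of that year, January-July to the
#' preceding one) and counts distinct wintering sites per winter. The
#' first-occupied site is retained for site-fidelity analyses.
#'
#' @param segmentation Result of [segmentAnnualCycle()], or a compatible
#'   phase data.frame.
#' @return data.frame: `individual_id`, `winter`, `n_sites`, `multi_site`,
#'   `first_site_id`, `first_site_lon`, `first_site_lat`.
#' @export
siteInventory <- function(segmentation) {
  phases <- if (is.data.frame(segmentation)) segmentation else segmentation$phases
  w <- phases[phases$phase == "wintering", , drop = FALSE]
  if (is.null(w) || !nrow(w))
    return(data.frame(individual_id = character(), winter = character(),
                      n_sites = integer(), multi_site = logical(),
                      first_site_id = character(), first_site_lon = numeric(),
                      first_site_lat = numeric()))
  start <- as.Date(w$first_signal)
  mon <- as.integer(format(start, "%m"))
  yr <- as.integer(format(start, "%Y"))
  wy <- ifelse(mon >= 8, yr, yr - 1L)
  w$winter <- sprintf("%d/%02d", wy, (wy + 1L) %% 100)
  out <- NULL
  for (key in unique(paste(w$individual_id, w$winter))) {
    sub <- w[paste(w$individual_id, w$winter) == key, , drop = FALSE]
    sub <- sub[order(sub$first_signal), , drop = FALSE]
    nSites <- length(unique(stats::na.omit(sub$site_id)))
    if (!nSites) nSites <- nrow(sub)
    out <- rbind(out, data.frame(
      individual_id = sub$individual_id[1], winter = sub$winter[1],
      n_sites = nSites, multi_site = nSites > 1,
      first_site_id = sub$site_id[1],
      first_site_lon = sub$site_lon[1], first_site_lat = sub$site_lat[1],
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
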