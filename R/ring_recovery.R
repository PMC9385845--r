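# Mark-recovery analysis: seasonal/span/accuracy filters, great-circle
# recovery lines, line-density rasters and recovery-position kernel
# densities. Country assignment comes from the record fields; no political
# boundaries are bundled.

.inBreedingWindow <- function(d) {
  m <- as.integer(format(d, "%m"))
  m >= 4 & m <= 9  # 01 Apr - 30 Sep
}

# Germany winter window: 01 Nov - end Feb ("30 February" read as month end);
# elsewhere: 01 Oct - 30 Mar (literal).
.inWinterWindow <- function(d, country) {
  m <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  ifelse(country == "DE",
         m %in% c(11, 12, 1, 2),
         m %in% c(10, 11, 12, 1, 2) | (m == 3 & day <= 30))
}

.addYears <- function(d, k) {
  lt <- as.POSIXlt(d)
  lt$year <- lt$year + k
  bad <- lt$mon == 1 & lt$mday == 29  # Feb 29 anniversaries
  lt$mday[bad] <- 28
  as.Date(lt)
}

#' Filter ring recoveries by season, span and date accuracy
#'
#' Keeps records that match either direction of the breeding-to-wintering
#' scheme: (a) ringed in Germany during the breeding season (01 Apr-30 Sep)
#' and recovered in the wintering season (within Germany 01 Nov-end Feb;
#' any other country 01 Oct-30 Mar), or (b) ringed anywhere in the
#' applicable wintering window and recovered in Germany during the breeding
#' window. Records with more than 5 years between ringing and recovery, or
#' a date accuracy worse than 6 weeks (42 days), are discarded. Every
#' dropped record carries exactly one primary reason with priority
#' `malformed > season > span > accuracy`; verdicts are independent of the
#' record order.
#'
#' @param records data.frame with the columns of
#'   [simulateRingRecoveries()] (at least ring/recovery dates, coordinates,
#'   countries and `date_accuracy_days`).
#' @return The input with `verdict` (`"kept"`/`"dropped"`) and `reason`
#'   columns appended.
#' @export
filterRecoveries <- function(records) {
  need <- c("ring_date", "recovery_date", "ring_lon", "ring_lat",
            "recovery_lon", "recovery_lat", "ring_country",
            "recovery_country", "date_accuracy_days")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rd <- as.Date(records$ring_date)
  cd <- as.Date(records$recovery_date)
  malformed <- is.na(rd) | is.na(cd) |
    !is.finite(records$ring_lon) | !is.finite(records$ring_lat) |
    !is.finite(records$recovery_lon) | !is.finite(records$recovery_lat)
  dirA <- records$ring_country == "DE" & .inBreedingWindow(rd) &
    .inWinterWindow(cd, records$recovery_country)
  dirB <- .inWinterWindow(rd, records$ring_country) &
    records$recovery_country == "DE" & .inBreedingWindow(cd)
  season <- !malformed & !(dirA %in% TRUE | dirB %in% TRUE)
  span <- !malformed & ((cd > .addYears(rd, 5)) %in% TRUE | (cd < rd) %in% TRUE)
  accuracy <- (records$date_accuracy_days > 42) %in% TRUE
  reason <- rep(NA_character_, nrow(records))
  reason[accuracy] <- "accuracy"
  reason[span] <- "span"
  reason[season] <- "season"
  reason[malformed] <- "malformed"
  records$verdict <- ifelse(is.na(reason), "kept", "dropped")
  records$reason <- reason
  records
}

#' Great-circle recovery lines
#'
#' Builds a densified great-circle polyline between each kept record's
#' ringing and recovery positions (vertices at most `step_km` apart).
#' Coincident endpoints yield a zero-length line, which is kept.
#'
#' @param records Kept records (use `verdict == "kept"` rows of
#'   [filterRecoveries()] output).
#' @param step_km Maximum vertex spacing along the line (10 km).
#' @return list of class `recoveryLines`: per record a matrix of lon/lat
#'   vertices, named by `ring_id`.
#' @export
recoveryLines <- function(records, step_km = 10) {
  stopifnot(step_km > 0)
  out <- lapply(seq_len(nrow(records)), function(i) {
    d <- haversineM(records$ring_lon[i], records$ring_lat[i],
                    records$recovery_lon[i], records$recovery_lat[i])
    nseg <- max(1, ceiling(d / (step_km * 1000)))
    greatCircleInterp(records$ring_lon[i], records$ring_lat[i],
                      records$recovery_lon[i], records$recovery_lat[i],
                      seq(0, 1, length.out = nseg + 1))
  })
  names(out) <- if ("ring_id" %in% names(records)) records$ring_id else
    as.character(seq_len(nrow(records)))
  structure(out, class = "recoveryLines")
}

#' @export
print.recoveryLines <- function(x, ...) {
  cat("Recovery lines:", length(x), "great-circle polylines\n")
  invisible(x)
}

#' Total length of each recovery line (metres)
#'
#' @param lines A [recoveryLines()] object.
#' @return Numeric vector of polyline lengths.
#' @export
lineLengthsM <- function(lines) {
  vapply(lines, function(m) {
    if (nrow(m) < 2) return(0)
    sum(haversineM(m[-nrow(m), "lon"], m[-nrow(m), "lat"],
                   m[-1, "lon"], m[-1, "lat"]))
  }, numeric(1))
}

#' Line density of mark-recovery lines
#'
#' Standard line-density semantics: for each cell, the total length of line
#' segments within `radius_m` of the cell centre divided by the search-disc
#' area, in km per km^2. Lines are projected to the shared azimuthal
#' equal-area plane (centred on the mean of all vertices) before the planar
#' length computation; segment-in-circle lengths are exact chord
#' intersections.
#'
#' @param lines A [recoveryLines()] object.
#' @param cell_size_m Output cell size (metres).
#' @param radius_m Search radius (metres).
#' @param pad_m Extent padding around the vertex bounding box (defaults to
#'   `radius_m`).
#' @return list of class `lineDensity`: `grid` (an [asciiGrid()] in
#'   projected metres, row 1 north), `lon0`, `lat0`, `radius_m`.
#' @export
lineDensity <- function(lines, cell_size_m, radius_m, pad_m = radius_m) {
  if (radius_m <= 0) stop("radius must be positive")
  verts <- do.call(rbind, lines)
  lon0 <- mean(verts[, "lon"]); lat0 <- mean(verts[, "lat"])
  proj <- lapply(lines, function(m) projectAEQ(m[, "lon"], m[, "lat"], lon0, lat0))
  allxy <- do.call(rbind, proj)
  xr <- range(allxy[, 1]) + c(-pad_m, pad_m)
  yr <- range(allxy[, 2]) + c(-pad_m, pad_m)
  nx <- max(1L, ceiling(diff(xr) / cell_size_m))
  ny <- max(1L, ceiling(diff(yr) / cell_size_m))
  xc <- xr[1] + (seq_len(nx) - 0.5) * cell_size_m
  yc <- yr[1] + (seq_len(ny) - 0.5) * cell_size_m
  acc <- matrix(0, ny, nx)  # [row = y from north]
  for (m in proj) {
    if (nrow(m) < 2) next
    for (s in seq_len(nrow(m) - 1)) {
      p1 <- m[s, ]; p2 <- m[s + 1, ]
      u <- p2 - p1
      L <- sqrt(sum(u^2))
      if (L == 0) next
      u <- u / L
      jx <- which(xc >= min(p1[1], p2[1]) - radius_m &
                    xc <= max(p1[1], p2[1]) + radius_m)
      jy <- which(yc >= min(p1[2], p2[2]) - radius_m &
                    yc <= max(p1[2], p2[2]) + radius_m)
      if (!length(jx) || !length(jy)) next
      for (iy in jy) {
        # closed-form |p1 + t u - c| <= r over t in [0, L]
        wx <- xc[jx] - p1[1]; wy <- yc[iy] - p1[2]
        tproj <- wx * u[1] + wy * u[2]
        d2 <- (wx^2 + wy^2) - tproj^2
        disc <- radius_m^2 - d2
        hit <- disc > 0
        if (!any(hit)) next
        half <- sqrt(disc[hit])
        t0 <- pmax(0, tproj[hit] - half)
        t1 <- pmin(L, tproj[hit] + half)
        len <- pmax(0, t1 - t0)
        row <- ny - iy + 1
        acc[row, jx[hit]] <- acc[row, jx[hit]] + len
      }
    }
  }
  dens <- (acc / 1000) / (pi * (radius_m / 1000)^2)  # km per km^2
  structure(list(grid = asciiGrid(dens, xr[1], yr[1], cell_size_m),
                 lon0 = lon0, lat0 = lat0, radius_m = radius_m),
            class = "lineDensity")
}

#' Kernel density of recovery positions
#'
#' Bivariate-normal kernel UD of the recovery coordinates (grid of
#' `grid_cells` per side, href bandwidth) with 50% and 95% volume contours,
#' to display the main wintering regions of recovered birds.
#'
#' @param records Kept records (typically the abroad winter recoveries).
#' @param grid_cells Cells per grid side (100).
#' @param levels Contour levels (0.50 and 0.95).
#' @return list: `ud` ([UDSurface-class]) and one [HomeRange-class] per
#'   level (named e.g. `"50%"`, `"95%"`).
#' @export
recoveryPositionKDE <- function(records, grid_cells = 100,
                                levels = c(0.5, 0.95)) {
  if (nrow(records) < 5) stop("need at least 5 recovery positions")
  ud <- kernelUD(records$recovery_lon, records$recovery_lat,
                 grid_cells = grid_cells, kernel = "bivnorm")
  contours <- lapply(levels, function(l) volumeContour(ud, l))
  names(contours) <- sprintf("%.0f%%", 100 * levels)
  c(list(ud = ud), contours)
}

#' Recovery proportions within/outside the ringing country
#'
#' @param records Kept records.
#' @return list of class `recoveryProportions`: `n`, `p_within`,
#'   `p_outside`, `abroad` (data.frame `country`, `n`, `fraction` of the
#'   abroad records).
#' @export
recoveryProportions <- function(records) {
  if (!nrow(records))
    return(structure(list(n = 0L, p_within = NA_real_, p_outside = NA_real_,
                          abroad = NULL), class = "recoveryProportions"))
  within <- records$recovery_country == records$ring_country
  ab <- records$recovery_country[!within]
  abroad <- NULL
  if (length(ab)) {
    tb <- sort(table(ab), decreasing = TRUE)
    abroad <- data.frame(country = names(tb), n = as.integer(tb),
                         fraction = as.numeric(tb) / length(ab),
                         stringsAsFactors = FALSE)
  }
  structure(list(n = nrow(records), p_within = mean(within),
                 p_outside = mean(!within), abroad = abroad),
            class = "recoveryProportions")
}

#' @export
print.recoveryProportions <- function(x, ...) {
  cat(sprintf("Ring recoveries kept: %d (%.0f%% within, %.0f%% outside the ringing country)\n",
              x$n, 100 * x$p_within, 100 * x$p_outside))
  if (!is.null(x$abroad))
    for (i in seq_len(nrow(x$abroad)))
      cat(sprintf("  abroad: %s %.0f%%\n", x$abroad$country[i],
                  100 * x$abroad$fraction[i]))
  invisible(x)
}
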