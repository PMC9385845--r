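# Reading tracking data and the two deterministic location-quality filters:
# the Argos location-class filter (keep LC 3/2/1) and the 30 m/s speed sweep.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

newFilterReport <- function(n_input, n_removed_lc = 0L, n_removed_speed = 0L,
                            n_removed_duplicate = 0L) {
  structure(list(n_input = as.integer(n_input),
                 n_removed_lc = as.integer(n_removed_lc),
                 n_removed_speed = as.integer(n_removed_speed),
                 n_removed_duplicate = as.integer(n_removed_duplicate),
                 n_retained = as.integer(n_input - n_removed_lc -
                                           n_removed_speed - n_removed_duplicate)),
            class = "filterReport")
}

#' @export
print.filterReport <- function(x, ...) {
  cat("Location filter report:\n")
  cat(sprintf("  input     %6d\n", x$n_input))
  cat(sprintf("  - LC      %6d\n  - speed   %6d\n  - dupes   %6d\n",
              x$n_removed_lc, x$n_removed_speed, x$n_removed_duplicate))
  cat(sprintf("  retained  %6d\n", x$n_retained))
  invisible(x)
}

.checkTrackColumns <- function(df, path = "<data.frame>") {
  need <- c("individual_id", "timestamp", "lon", "lat", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
}

#' Read tracking locations from delimited text
#'
#' Expects Movebank-style columns `individual_id, timestamp, lon, lat, source`
#' and optionally `lc` (Argos location class). Timestamps are ISO-8601 and
#' interpreted as UTC. Rows are sorted by individual and time; duplicate
#' (individual, timestamp) rows are collapsed to their first occurrence and
#' counted in the attached filter report (`attr(x, "report")`).
#'
#' @param path Path to a CSV file.
#' @param sep Field separator (default comma).
#' @return A `data.frame` of locations with attribute `report`
#'   (a `filterReport`).
#' @export
readTracks <- function(path, sep = ",") {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .checkTrackColumns(df, path)
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(strptime(df$timestamp[need], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad))
    stop(sprintf("%s: unparseable timestamp at row %d ('%s')",
                 path, bad[1], df$timestamp[bad[1]]))
  badlat <- which(!is.finite(df$lat) | df$lat < -90 | df$lat > 90)
  if (length(badlat))
    stop(sprintf("%s: latitude out of range at row %d (%s)",
                 path, badlat[1], df$lat[badlat[1]]))
  badlon <- which(!is.finite(df$lon) | df$lon < -180 | df$lon > 180)
  if (length(badlon))
    stop(sprintf("%s: longitude out of range at row %d (%s)",
                 path, badlon[1], df$lon[badlon[1]]))
  badsrc <- which(!df$source %in% c("gps", "argos"))
  if (length(badsrc))
    stop(sprintf("%s: unknown source at row %d ('%s'); expected gps|argos",
                 path, badsrc[1], df$source[badsrc[1]]))
  df$timestamp <- ts
  if (!"lc" %in% names(df)) df$lc <- NA_character_ else df$lc <- as.character(df$lc)
  df <- df[order(df$individual_id, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[, c("individual_id", "timestamp")])
  out <- df[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- newFilterReport(nrow(df), n_removed_duplicate = sum(dup))
  out
}

#' Write tracking locations as CSV
#'
#' Inverse of [readTracks()]; internal simulation columns (`true_lon`,
#' `true_lat`, `outlier`) are dropped so files round-trip through the
#' documented column contract.
#'
#' @param tracks Location data.frame.
#' @param path Output path.
#' @export
writeTracksCSV <- function(tracks, path) {
  keep <- intersect(c("individual_id", "timestamp", "lon", "lat", "source", "lc"),
                    names(tracks))
  out <- tracks[, keep, drop = FALSE]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Filter Argos fixes by location class
#'
#' Retains Argos rows whose location class is in `allowed` (by default the
#' three highest-quality classes 3, 2 and 1); GPS rows pass unchanged. An
#' Argos row without a location class is an error.
#'
#' @param tracks Location data.frame (see [readTracks()]).
#' @param allowed Character vector of admissible classes.
#' @return `list(tracks =, report =)` with a [print.filterReport()] report.
#' @export
filterArgosLC <- function(tracks, allowed = c("3", "2", "1")) {
  .checkTrackColumns(tracks)
  allowed <- as.character(allowed)
  stopifnot(all(allowed %in% ARGOS_CLASSES))
  isArgos <- tracks$source == "argos"
  if (any(isArgos & (is.na(tracks$lc) | tracks$lc == "")))
    stop("argos row without a location class at row ",
         which(isArgos & (is.na(tracks$lc) | tracks$lc == ""))[1])
  drop <- isArgos & !(tracks$lc %in% allowed)
  out <- tracks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(tracks = out,
       report = newFilterReport(nrow(tracks), n_removed_lc = sum(drop)))
}

#' Speed filter (30 m/s sweep)
#'
#' Forward sweep per individual: a fix whose great-circle speed from the last
#' *retained* fix exceeds `vmax` is removed, so an isolated displaced fix
#' costs exactly one location. Fixes with a non-positive time difference from
#' the last retained fix are removed and counted as duplicates. The sweep is
#' idempotent and never lets one individual's fixes influence another's.
#'
#' @param tracks Location data.frame, time-sorted within individuals.
#' @param vmax Speed ceiling in m/s; the default 30 m/s is a realistic upper
#'   bound on sustained pigeon flight speed.
#' @return `list(tracks =, report =)`.
#' @export
speedFilter <- function(tracks, vmax = 30) {
  .checkTrackColumns(tracks)
  stopifnot(vmax > 0)
  keep <- logical(nrow(tracks))
  nSpeed <- 0L; nDup <- 0L
  for (id in unique(tracks$individual_id)) {
    idx <- which(tracks$individual_id == id)
    if (!length(idx)) next
    lastKept <- idx[1]
    keep[lastKept] <- TRUE
    for (i in idx[-1]) {
      dt <- as.numeric(difftime(tracks$timestamp[i], tracks$timestamp[lastKept],
                                units = "secs"))
      if (dt <= 0) { nDup <- nDup + 1L; next }
      d <- haversineM(tracks$lon[lastKept], tracks$lat[lastKept],
                      tracks$lon[i], tracks$lat[i])
      if (d / dt > vmax) { nSpeed <- nSpeed + 1L; next }
      keep[i] <- TRUE
      lastKept <- i
    }
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(tracks = out,
       report = newFilterReport(nrow(tracks), n_removed_speed = nSpeed,
                                n_removed_duplicate = nDup))
}
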