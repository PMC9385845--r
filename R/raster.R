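# Minimal categorical-raster support: the ESRI ASCII grid dialect (the
# interchange format used for land-cover extracts) and a synthetic
# CORINE-style land-cover generator. No raster package ships with the
# target environment, and the format is trivial, so it is read and written
# directly.

#' Construct an ESRI ASCII grid object
#'
#' @param values Numeric matrix; row 1 is the northernmost row, as in the
#'   file format.
#' @param xllcorner,yllcorner Lower-left corner of the grid (degrees or
#'   metres, depending on use).
#' @param cellsize Cell edge length (same units as the corner).
#' @param nodata NODATA sentinel value.
#' @return A list of class `asciiGrid`.
#' @export
asciiGrid <- function(values, xllcorner, yllcorner, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(ncols = ncol(values), nrows = nrow(values),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata, values = values),
            class = "asciiGrid")
}

#' @export
print.asciiGrid <- function(x, ...) {
  cat(sprintf("ESRI ASCII grid: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              x$ncols, x$nrows, x$cellsize, x$xllcorner, x$yllcorner))
  invisible(x)
}

#' Write an ESRI ASCII grid
#'
#' @param grid An [asciiGrid()].
#' @param path Output path.
#' @export
writeAsciiGrid <- function(grid, path) {
  stopifnot(inherits(grid, "asciiGrid"))
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.10g", grid$xllcorner),
           sprintf("yllcorner %.10g", grid$yllcorner),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %g", grid$nodata))
  rows <- apply(grid$values, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @return An [asciiGrid()].
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (nrow(vals) != hdr$nrows || ncol(vals) != hdr$ncols)
    stop("ASCII grid dimensions disagree with header in ", path)
  asciiGrid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
            if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value)
}

#' Look up raster values at point coordinates
#'
#' @param grid An [asciiGrid()].
#' @param x,y Coordinates in the grid's units (lon/lat for geographic grids).
#' @param outside How to treat points beyond the raster: `"na"` or `"error"`.
#' @return Numeric vector of cell values (`NA` for NODATA).
#' @export
gridLookup <- function(grid, x, y, outside = c("na", "error")) {
  outside <- match.arg(outside)
  col <- floor((x - grid$xllcorner) / grid$cellsize) + 1
  rowb <- floor((y - grid$yllcorner) / grid$cellsize) + 1
  bad <- col < 1 | col > grid$ncols | rowb < 1 | rowb > grid$nrows
  if (any(bad) && outside == "error")
    stop(sprintf("point (%.5f, %.5f) lies outside the raster extent",
                 x[which(bad)[1]], y[which(bad)[1]]))
  row <- grid$nrows - rowb + 1
  out <- rep(NA_real_, length(x))
  ok <- !bad
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out[out == grid$nodata] <- NA
  out
}

#' Cell-centre coordinates of a grid
#'
#' @param grid An [asciiGrid()].
#' @return `list(x =, y =)` of cell-centre coordinate vectors (x along
#'   columns west-to-east, y along rows south-to-north).
#' @export
gridCenters <- function(grid) {
  list(x = grid$xllcorner + (seq_len(grid$ncols) - 0.5) * grid$cellsize,
       y = grid$yllcorner + (seq_len(grid$nrows) - 0.5) * grid$cellsize)
}

# CORINE-style class codes used by the synthetic generator. Level-1 class is
# the leading digit: 1 artificial, 2 agricultural, 3 forest/semi-natural.
CLC_URBAN_FABRIC <- 112
CLC_GREEN_URBAN <- 141
CLC_ARABLE <- 211
CLC_FOREST <- 311

#' Simulate a CORINE-style categorical land-cover raster
#'
#' Builds a simple concentric landscape: artificial surfaces (urban fabric,
#' code 112) within `city_radius_km` of the city centre, with a green-urban
#' patch (141) inside the city; an agricultural ring (non-irrigated arable
#' land, 211) out to `agri_outer_km`; broad-leaved forest (311) beyond.
#' Class codes follow the three-level CORINE numbering, so the leading digit
#' is the level-1 class (1 = artificial surfaces, 2 = agricultural areas).
#'
#' @param extent `c(lonmin, lonmax, latmin, latmax)` in degrees.
#' @param cell_size Cell size in degrees.
#' @param city_center `c(lon, lat)` of the city.
#' @param city_radius_km Radius of the artificial-surface disc.
#' @param agri_outer_km Outer radius of the agricultural ring (default 3x
#'   the city radius).
#' @param green_frac Radius of the green-urban patch as a fraction of
#'   `city_radius_km` (patch centre offset by 0.4 city radii, so it stays
#'   inside the city).
#' @return An [asciiGrid()] of integer class codes (geographic lon/lat grid).
#' @export
simulateLandcover <- function(extent, cell_size, city_center, city_radius_km,
                              agri_outer_km = 3 * city_radius_km,
                              green_frac = 0.3) {
  stopifnot(length(extent) == 4, cell_size > 0)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("zero-area extent")
  inside <- city_center[1] > extent[1] && city_center[1] < extent[2] &&
    city_center[2] > extent[3] && city_center[2] < extent[4]
  if (!inside) stop("city centre must lie inside the extent")
  ncols <- max(1L, round((extent[2] - extent[1]) / cell_size))
  nrows <- max(1L, round((extent[4] - extent[3]) / cell_size))
  cx <- extent[1] + (seq_len(ncols) - 0.5) * cell_size
  cy <- extent[3] + (seq_len(nrows) - 0.5) * cell_size
  lon <- matrix(rep(cx, each = nrows), nrows, ncols)
  lat <- matrix(rep(rev(cy), ncols), nrows, ncols)  # row 1 = north
  dCity <- haversineM(lon, lat, city_center[1], city_center[2]) / 1000
  gc <- destinationPoint(city_center[1], city_center[2], 45,
                         0.4 * city_radius_km * 1000)
  dGreen <- haversineM(lon, lat, gc[1, "lon"], gc[1, "lat"]) / 1000
  vals <- matrix(CLC_FOREST, nrows, ncols)
  vals[dCity <= agri_outer_km] <- CLC_ARABLE
  vals[dCity <= city_radius_km] <- CLC_URBAN_FABRIC
  vals[dGreen <= green_frac * city_radius_km] <- CLC_GREEN_URBAN
  asciiGrid(vals, extent[1], extent[3], cell_size)
}

#' Simulate ring-recovery records
#'
#' Generates mark-recovery pairs emulating a European ringing-scheme
#' extract: birds ringed in the German breeding season (Apr-Sep) and
#' recovered in the wintering season, abroad with probability `p_abroad`
#' (country drawn from `country_weights`, positions scattered around
#' country-specific wintering centres). A configurable fraction of records
#' violates exactly one of the downstream filter rules (wrong season, span
#' over five years, date accuracy worse than six weeks); the injected truth
#' is recorded in the `truth_violation` column so filter behaviour can be
#' checked against it.
#'
#' @param n Number of records.
#' @param p_abroad Probability a recovery falls outside Germany.
#' @param country_weights Named weights (summing to 1) over abroad countries.
#' @param seed Integer seed.
#' @param violation_rate Fraction of records that violate a filter rule
#'   (split equally across the three rules).
#' @return data.frame with columns `ring_id`, `ring_date`, `ring_lon`,
#'   `ring_lat`, `ring_country`, `recovery_date`, `recovery_lon`,
#'   `recovery_lat`, `recovery_country`, `date_accuracy_days`,
#'   `truth_violation`.
#' @export
simulateRingRecoveries <- function(n, p_abroad = 0.72,
                                   country_weights = c(FR = 0.85, ES = 0.05,
                                                       BE = 0.04, NL = 0.03,
                                                       DK = 0.03),
                                   seed = 1L, violation_rate = 0) {
  if (abs(sum(country_weights) - 1) > 1e-8)
    stop("country_weights must sum to 1")
  if (p_abroad < 0 || p_abroad > 1 || violation_rate < 0 || violation_rate > 1)
    stop("probabilities must be in [0, 1]")
  centres <- list(FR = c(0.0, 44.5), ES = c(-3.7, 40.4), BE = c(4.5, 50.5),
                  NL = c(5.3, 52.1), DK = c(9.0, 56.0), PT = c(-8.0, 39.5))
  .withSeed(seed, {
    ringYear <- sample(1960:2014, n, replace = TRUE)
    ringDate <- as.Date(sprintf("%d-01-01", ringYear)) +
      sample(91:272, n, replace = TRUE)  # Apr 1 - Sep 29
    ringLon <- stats::runif(n, 6.5, 13.5)
    ringLat <- stats::runif(n, 47.8, 54.2)
    abroad <- stats::runif(n) < p_abroad
    country <- ifelse(abroad,
                      sample(names(country_weights), n, replace = TRUE,
                             prob = country_weights),
                      "DE")
    span <- sample(0:4, n, replace = TRUE)
    # recovery date inside the applicable winter window
    recDate <- as.Date(rep(NA, n))
    recLon <- recLat <- numeric(n)
    for (i in seq_len(n)) {
      y <- ringYear[i] + span[i]
      if (country[i] == "DE") {
        # Nov 1 (year y) .. end Feb (year y+1)
        offs <- sample(0:119, 1)
        recDate[i] <- as.Date(sprintf("%d-11-01", y)) + offs
        p <- destinationPoint(ringLon[i], ringLat[i],
                              stats::runif(1, 0, 360),
                              stats::runif(1, 5, 250) * 1000)
        recLon[i] <- p[1, "lon"]; recLat[i] <- p[1, "lat"]
      } else {
        offs <- sample(0:179, 1)  # Oct 1 .. end Mar (day 180 = Mar 29/30)
        recDate[i] <- as.Date(sprintf("%d-10-01", y)) + offs
        ctr <- centres[[country[i]]]
        off <- stats::rnorm(2, 0, 120 * 1000)
        ll <- unprojectAEQ(off[1], off[2], ctr[1], ctr[2])
        recLon[i] <- ll[1, "lon"]; recLat[i] <- ll[1, "lat"]
      }
    }
    accuracy <- sample(0:21, n, replace = TRUE)
    violation <- rep("none", n)
    nViol <- round(violation_rate * n)
    if (nViol > 0) {
      vIdx <- sample(n, nViol)
      vType <- rep_len(c("season", "span", "accuracy"), nViol)
      for (k in seq_along(vIdx)) {
        i <- vIdx[k]
        violation[i] <- vType[k]
        if (vType[k] == "season") {
          recDate[i] <- as.Date(sprintf("%d-06-15", ringYear[i] + span[i])) +
            sample(-30:30, 1)
        } else if (vType[k] == "span") {
          lt <- as.POSIXlt(recDate[i])
          lt$year <- lt$year + sample(6:8, 1)
          if (lt$mon == 1 && lt$mday == 29) lt$mday <- 28  # Feb 29 safety
          recDate[i] <- as.Date(lt)
        } else {
          accuracy[i] <- sample(50:120, 1)
        }
      }
    }
    data.frame(ring_id = sprintf("R%05d", seq_len(n)),
               ring_date = ringDate, ring_lon = ringLon, ring_lat = ringLat,
               ring_country = "DE",
               recovery_date = recDate, recovery_lon = recLon,
               recovery_lat = recLat, recovery_country = country,
               date_accuracy_days = accuracy,
               truth_violation = violation, stringsAsFactors = FALSE)
  })
}
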