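# City-to-farmland foraging structure: monthly 95% home ranges are split
# into parts lying on artificial surfaces ("city") and agricultural areas
# ("farmland"); the centroid-to-centroid vector gives commute distance and
# bearing, and pooled bearings feed the Rayleigh test.

#' Partition a home range into city and farmland parts
#'
#' Each rook-adjacent part of the contour is assigned the land-cover
#' level-1 class that covers the majority of its cells: artificial surfaces
#' (level 1) are "city", agricultural areas (level 2) "farmland", anything
#' else "other". The city footprint is thus defined by the land-cover
#' raster, not an administrative boundary.
#'
#' @param hr A [HomeRange-class] (typically a monthly 95% contour).
#' @param grid Land-cover [asciiGrid()] covering the contour.
#' @return list: `city`, `farm`, `other` (cell data.frames, possibly empty),
#'   `city_centroid`, `farm_centroid` (lon/lat or `NULL`),
#'   `component_class` (data.frame part -> class).
#' @export
partitionHomeRange <- function(hr, grid) {
  cl <- hr@cells
  if (!nrow(cl)) stop("empty home range")
  codes <- gridLookup(grid, cl$lon, cl$lat, outside = "na")
  if (any(is.na(codes)))
    stop("home range extends beyond the land-cover raster")
  lv <- codes %/% 100
  compClass <- vapply(split(lv, cl$component), function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    as.integer(names(tb)[1])
  }, integer(1))
  cls <- compClass[as.character(cl$component)]
  city <- cl[cls == 1, , drop = FALSE]
  farm <- cl[cls == 2, , drop = FALSE]
  other <- cl[!cls %in% c(1, 2), , drop = FALSE]
  centroid <- function(sub) {
    if (!nrow(sub)) return(NULL)
    ll <- unprojectAEQ(mean(sub$x), mean(sub$y), hr@lon0, hr@lat0)
    c(lon = unname(ll[1, "lon"]), lat = unname(ll[1, "lat"]))
  }
  list(city = city, farm = farm, other = other,
       city_centroid = centroid(city), farm_centroid = centroid(farm),
       component_class = data.frame(component = as.integer(names(compClass)),
                                    level1 = unname(compClass)))
}

#' Foraging vector between city and farmland home-range parts
#'
#' Distance (great-circle, km) and initial bearing (degrees clockwise from
#' North) from the area-weighted centroid of the city parts to that of the
#' farmland parts.
#'
#' @param partition Result of [partitionHomeRange()], or a list with
#'   `city_centroid` and `farm_centroid` elements.
#' @param individual,month Optional labels.
#' @return One-row data.frame `individual_id`, `month`, `city_lon`,
#'   `city_lat`, `farm_lon`, `farm_lat`, `distance_km`, `bearing_deg`;
#'   `NULL` when there is no farmland part. Coincident centroids give
#'   `bearing_deg = NA` (flagged, excluded from circular statistics).
#' @export
foragingVector <- function(partition, individual = NA_character_,
                           month = NA_character_) {
  cc <- partition$city_centroid; fc <- partition$farm_centroid
  if (is.null(fc) || is.null(cc)) return(NULL)
  d <- haversineM(cc["lon"], cc["lat"], fc["lon"], fc["lat"]) / 1000
  b <- if (d < 1e-9) NA_real_ else
    initialBearing(cc["lon"], cc["lat"], fc["lon"], fc["lat"])
  data.frame(individual_id = individual, month = month,
             city_lon = unname(cc["lon"]), city_lat = unname(cc["lat"]),
             farm_lon = unname(fc["lon"]), farm_lat = unname(fc["lat"]),
             distance_km = unname(d), bearing_deg = unname(b),
             stringsAsFactors = FALSE)
}

#' Monthly foraging vectors for a set of home ranges
#'
#' Applies [partitionHomeRange()] and [foragingVector()] to each monthly
#' home range; months without a farmland part yield no vector but are
#' counted in the denominator of the proportion of months in which the bird
#' left the city.
#'
#' @param hrList List of [HomeRange-class] objects (with `individual` and
#'   `month` labels set).
#' @param grid Land-cover [asciiGrid()].
#' @return list: `vectors` (data.frame), `n_months`, `n_outside`,
#'   `prop_outside`.
#' @export
foragingVectors <- function(hrList, grid) {
  vecs <- NULL
  nOut <- 0L
  for (hr in hrList) {
    part <- partitionHomeRange(hr, grid)
    v <- foragingVector(part, hr@individual, hr@month)
    if (!is.null(v)) {
      nOut <- nOut + 1L
      vecs <- rbind(vecs, v)
    }
  }
  n <- length(hrList)
  list(vectors = vecs, n_months = n, n_outside = nOut,
       prop_outside = if (n) nOut / n else NA_real_)
}

#' Circular summary and Rayleigh test of bearings
#'
#' Mean direction `alpha = atan2(mean sin, mean cos)` mapped to [0, 360),
#' resultant length `r` (0 = uniform, 1 = perfectly concentrated),
#' `Z = n r^2`, and the Rayleigh p-value by the standard series
#' approximation
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]`,
#' clamped into (0, 1].
#'
#' @param bearings Bearings in degrees; `NA`s are dropped.
#' @return list of class `circularSummary`: `n`, `mean_direction`, `r`,
#'   `rayleigh_Z`, `rayleigh_p`.
#' @export
circularSummary <- function(bearings) {
  b <- bearings[is.finite(bearings)]
  n <- length(b)
  if (!n) stop("no finite bearings")
  th <- .deg2rad(b)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  alpha <- (.rad2deg(atan2(S, C)) + 360) %% 360
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 1e-300), 1)
  structure(list(n = n, mean_direction = alpha, r = r,
                 rayleigh_Z = Z, rayleigh_p = p),
            class = "circularSummary")
}

#' @export
print.circularSummary <- function(x, ...) {
  cat(sprintf(
    "Circular summary: n = %d, alpha = %.1f deg, r = %.3f, Z = %.2f, p = %.3g\n",
    x$n, x$mean_direction, x$r, x$rayleigh_Z, x$rayleigh_p))
  invisible(x)
}

#' Rose-diagram bin counts
#'
#' Counts bearings per sector for rose-diagram export (10 degree sectors by
#' default; sector k covers `[(k-1)w, kw)`).
#'
#' @param bearings Bearings in degrees.
#' @param width Sector width in degrees (must divide 360).
#' @return data.frame `sector_start`, `sector_end`, `count`.
#' @export
roseBins <- function(bearings, width = 10) {
  if (360 %% width != 0) stop("sector width must divide 360")
  b <- bearings[is.finite(bearings)] %% 360
  k <- floor(b / width)
  counts <- tabulate(k + 1, nbins = 360 / width)
  data.frame(sector_start = seq(0, 360 - width, by = width),
             sector_end = seq(width, 360, by = width),
             count = counts)
}
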