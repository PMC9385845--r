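# Spherical geodesy on the WGS84 equatorial radius. All angles in degrees,
# all distances in metres unless stated otherwise.

#' Sphere radius used throughout the package
#'
#' Great-circle computations use a sphere of radius 6,378,137 m (the WGS84
#' equatorial radius), the common geodesy default for movement data at the
#' continental scales handled here.
#'
#' @format A length-one numeric (metres).
#' @export
R_EARTH <- 6378137

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Great-circle (haversine) distance
#'
#' Distance between points on a sphere of radius [R_EARTH]. Vectorised over
#' all four coordinate arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84 lon/lat).
#' @return Distance(s) in metres.
#' @examples
#' haversineM(0, 0, 1, 0) # ~111.32 km, one degree along the equator
#' @export
haversineM <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dp <- p2 - p1
  dl <- .deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * R_EARTH * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Forward azimuth from the first point to the second, measured clockwise
#' from geographic North.
#'
#' @inheritParams haversineM
#' @return Bearing(s) in degrees within `[0, 360)`.
#' @export
initialBearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dl <- .deg2rad(lon2 - lon1)
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (.rad2deg(atan2(y, x)) + 360) %% 360
}

#' Destination point along a great circle
#'
#' @inheritParams haversineM
#' @param lon,lat Start point (degrees).
#' @param bearing Initial bearing in degrees (0 = North, clockwise).
#' @param distance Distance in metres.
#' @return A two-column matrix `cbind(lon, lat)` in degrees.
#' @export
destinationPoint <- function(lon, lat, bearing, distance) {
  d <- distance / R_EARTH
  th <- .deg2rad(bearing)
  p1 <- .deg2rad(lat); l1 <- .deg2rad(lon)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  cbind(lon = ((.rad2deg(l2) + 540) %% 360) - 180, lat = .rad2deg(p2))
}

#' Interpolate points along a great circle
#'
#' Spherical linear interpolation between two points; used to densify
#' mark-recovery lines and to move simulated birds along migration legs.
#'
#' @inheritParams haversineM
#' @param f Interpolation fraction(s) in `[0, 1]`.
#' @return A two-column matrix `cbind(lon, lat)`.
#' @export
greatCircleInterp <- function(lon1, lat1, lon2, lat2, f) {
  p1 <- .deg2rad(lat1); l1 <- .deg2rad(lon1)
  p2 <- .deg2rad(lat2); l2 <- .deg2rad(lon2)
  d <- haversineM(lon1, lat1, lon2, lat2) / R_EARTH
  if (d < 1e-12) return(cbind(lon = rep(lon1, length(f)), lat = rep(lat1, length(f))))
  A <- sin((1 - f) * d) / sin(d)
  B <- sin(f * d) / sin(d)
  x <- A * cos(p1) * cos(l1) + B * cos(p2) * cos(l2)
  y <- A * cos(p1) * sin(l1) + B * cos(p2) * sin(l2)
  z <- A * sin(p1) + B * sin(p2)
  cbind(lon = .rad2deg(atan2(y, x)), lat = .rad2deg(atan2(z, sqrt(x^2 + y^2))))
}

#' Lambert azimuthal equal-area projection
#'
#' Projects lon/lat onto a plane tangent at `(lon0, lat0)`. Equal-area, so
#' planar cell counts translate directly into true areas; this is the
#' projection behind every kernel-density and line-density grid in the
#' package.
#'
#' @param lon,lat Coordinates in degrees.
#' @param lon0,lat0 Projection centre in degrees.
#' @return Two-column matrix `cbind(x, y)` in metres.
#' @seealso [unprojectAEQ()]
#' @export
projectAEQ <- function(lon, lat, lon0, lat0) {
  p <- .deg2rad(lat); p0 <- .deg2rad(lat0)
  dl <- .deg2rad(lon - lon0)
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(dl)
  k <- sqrt(2 / pmax(denom, 1e-12))
  cbind(x = R_EARTH * k * cos(p) * sin(dl),
        y = R_EARTH * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(dl)))
}

#' Inverse Lambert azimuthal equal-area projection
#'
#' @param x,y Planar coordinates in metres.
#' @inheritParams projectAEQ
#' @return Two-column matrix `cbind(lon, lat)` in degrees.
#' @export
unprojectAEQ <- function(x, y, lon0, lat0) {
  p0 <- .deg2rad(lat0); l0 <- .deg2rad(lon0)
  rho <- sqrt(x^2 + y^2)
  c <- 2 * asin(pmin(1, rho / (2 * R_EARTH)))
  lat <- ifelse(rho < 1e-9, lat0,
                .rad2deg(asin(cos(c) * sin(p0) + y * sin(c) * cos(p0) / pmax(rho, 1e-9))))
  lon <- ifelse(rho < 1e-9, lon0,
                .rad2deg(l0 + atan2(x * sin(c),
                                    rho * cos(p0) * cos(c) - y * sin(p0) * sin(c))))
  cbind(lon = lon, lat = lat)
}
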