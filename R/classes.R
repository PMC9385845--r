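# S4 containers for the kernel home-range machinery. Grids live in a local
# Lambert azimuthal equal-area plane whose centre (lon0/lat0) is carried in
# the object, so cells can always be mapped back to WGS84.

#' @import methods
NULL

#' UDSurface: a gridded kernel utilization distribution
#'
#' Probability-mass surface of an animal's space use on a square planar grid
#' (equal-area projection centred on the data). The density integrates to 1
#' over the grid; `density[i, j]` is probability density (per m^2) at the
#' centre of the cell in column `i` (x) and row `j` (y).
#'
#' @slot density Numeric matrix (nx by ny) of probability densities, >= 0.
#' @slot xmin,ymin Lower-left corner of the grid (metres, projected plane).
#' @slot cellSize Cell edge length in metres.
#' @slot kernel `"epanechnikov"` or `"bivnorm"`.
#' @slot h Smoothing bandwidth in metres (after any kernel rescaling).
#' @slot nPoints Number of relocations behind the estimate.
#' @slot lon0,lat0 Centre of the equal-area projection (degrees).
#' @seealso [kernelUD()], [volumeContour()]
#' @export
setClass("UDSurface",
  representation(density = "matrix", xmin = "numeric", ymin = "numeric",
                 cellSize = "numeric", kernel = "character", h = "numeric",
                 nPoints = "integer", lon0 = "numeric", lat0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@density < 0)) msg <- c(msg, "negative density values")
    if (length(object@cellSize) != 1 || object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a positive scalar")
    if (length(object@h) != 1 || object@h <= 0)
      msg <- c(msg, "bandwidth h must be positive")
    mass <- sum(object@density) * object@cellSize^2
    if (abs(mass - 1) > 1e-6)
      msg <- c(msg, sprintf("UD mass is %.8f, not 1 +/- 1e-6", mass))
    if (!object@kernel %in% c("epanechnikov", "bivnorm"))
      msg <- c(msg, "kernel must be 'epanechnikov' or 'bivnorm'")
    if (length(msg)) msg else TRUE
  })

#' HomeRange: a volume-contour set of a UDSurface
#'
#' The smallest set of grid cells whose cumulative (descending-density)
#' probability mass reaches `level`; the 95% contour is the conventional
#' home range, the 50% contour the core area. Cells are grouped into
#' rook-adjacent connected components ("parts"), the unit used when a home
#' range is split into city and farmland fractions.
#'
#' @slot level Contour level in (0, 1).
#' @slot cells data.frame with one row per selected cell: `ix`, `iy` (grid
#'   indices), `x`, `y` (projected cell centres, m), `lon`, `lat` (WGS84),
#'   `density`, `component` (integer part id).
#' @slot cellSize,xmin,ymin,lon0,lat0,kernel,h As in [UDSurface-class].
#' @slot gridDim Integer grid dimensions (nx, ny) of the parent surface.
#' @slot areaKm2 Total contour area in km^2 (cell count x cell area).
#' @slot individual,month Optional labels carried through monthly analyses.
#' @export
setClass("HomeRange",
  representation(level = "numeric", cells = "data.frame", cellSize = "numeric",
                 xmin = "numeric", ymin = "numeric", gridDim = "integer",
                 areaKm2 = "numeric", lon0 = "numeric", lat0 = "numeric",
                 kernel = "character", h = "numeric",
                 individual = "character", month = "character"),
  validity = function(object) {
    msg <- character()
    if (object@level <= 0 || object@level >= 1)
      msg <- c(msg, "level must be in (0, 1)")
    if (object@areaKm2 < 0) msg <- c(msg, "negative area")
    need <- c("ix", "iy", "x", "y", "lon", "lat", "density", "component")
    if (!all(need %in% names(object@cells)))
      msg <- c(msg, "cells is missing required columns")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "UDSurface", function(object) {
  cat("UDSurface:", paste(dim(object@density), collapse = " x "),
      "grid,", sprintf("cell %.1f m,", object@cellSize),
      object@kernel, "kernel,",
      sprintf("h = %.1f m, n = %d relocations\n", object@h, object@nPoints))
  cat(sprintf("  projection: azimuthal equal-area centred (%.4f, %.4f)\n",
              object@lon0, object@lat0))
})

setMethod("show", "HomeRange", function(object) {
  cat(sprintf("HomeRange: %.0f%% volume contour, %.3f km^2, %d cells in %d part(s)\n",
              100 * object@level, object@areaKm2, nrow(object@cells),
              length(unique(object@cells$component))))
  if (length(object@individual) && !is.na(object@individual[1]))
    cat("  individual:", object@individual[1],
        if (length(object@month) && !is.na(object@month[1])) paste0("month: ", object@month[1]) else "",
        "\n")
})

#' @describeIn HomeRange-class Contour area in km^2.
#' @param x A `HomeRange`.
#' @export
hrArea <- function(x) x@areaKm2

#' @describeIn HomeRange-class Contour level.
#' @export
hrLevel <- function(x) x@level

#' @describeIn HomeRange-class Selected cells (data.frame; see slot `cells`).
#' @export
hrCells <- function(x) x@cells

#' @describeIn UDSurface-class Density matrix accessor.
#' @param ud A `UDSurface`.
#' @export
udDensity <- function(ud) ud@density

#' @describeIn UDSurface-class Bandwidth accessor (metres).
#' @export
udBandwidth <- function(ud) ud@h

#' Area-weighted centroid of a home range (or a subset of its parts)
#'
#' Cells have equal area, so the centroid is the mean of the projected cell
#' centres, mapped back to WGS84.
#'
#' @param hr A [HomeRange-class].
#' @param components Optional integer vector of part ids to restrict to.
#' @return `c(lon, lat)` in degrees.
#' @export
hrCentroid <- function(hr, components = NULL) {
  cl <- hr@cells
  if (!is.null(components)) cl <- cl[cl$component %in% components, , drop = FALSE]
  if (!nrow(cl)) stop("no cells selected for centroid")
  ll <- unprojectAEQ(mean(cl$x), mean(cl$y), hr@lon0, hr@lat0)
  c(lon = unname(ll[1, "lon"]), lat = unname(ll[1, "lat"]))
}

#' Membership of points in a home-range contour
#'
#' Maps WGS84 points onto the grid of the parent utilization distribution and
#' reports whether each lands in a selected cell. Used, e.g., to check by
#' Monte Carlo that a 95% contour captures ~95% of fresh draws.
#'
#' @param hr A [HomeRange-class].
#' @param lon,lat Point coordinates in degrees.
#' @return Logical vector.
#' @export
pointsInHomeRange <- function(hr, lon, lat) {
  xy <- projectAEQ(lon, lat, hr@lon0, hr@lat0)
  ix <- floor((xy[, "x"] - hr@xmin) / hr@cellSize) + 1
  iy <- floor((xy[, "y"] - hr@ymin) / hr@cellSize) + 1
  key <- paste(ix, iy)
  key %in% paste(hr@cells$ix, hr@cells$iy)
}
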