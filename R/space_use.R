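# Kernel utilization distributions and home ranges. Points are projected to
# a local azimuthal equal-area plane centred on their centroid before any
# density estimation, so contour areas are true areas; the bivariate
# Epanechnikov kernel K(u) = (2/pi)(1 - u'u) on the unit disc is the default
# estimator, with the ad-hoc reference bandwidth href.

#' Reference (ad-hoc) bandwidth href
#'
#' `h = 0.5 * (sd_x + sd_y) * n^(-1/6)` for bivariate data. For the
#' Epanechnikov kernel the result is multiplied by 1.77, the conventional
#' rescaling that matches the Epanechnikov kernel's support to the Gaussian
#' bandwidth it was derived for.
#'
#' @param xy Two-column matrix of projected coordinates (metres).
#' @param kernel `"bivnorm"` or `"epanechnikov"`.
#' @return Bandwidth in metres.
#' @examples
#' # sd_x = sd_y = 1, n = 64: h = 64^(-1/6) = 0.5 for the Gaussian kernel
#' @export
hrefBandwidth <- function(xy, kernel = c("bivnorm", "epanechnikov")) {
  kernel <- match.arg(kernel)
  if (nrow(xy) < 5) stop("href needs at least 5 points")
  sx <- stats::sd(xy[, 1]); sy <- stats::sd(xy[, 2])
  if (sx == 0 && sy == 0) stop("degenerate point cloud: zero variance in both axes")
  h <- 0.5 * (sx + sy) * nrow(xy)^(-1 / 6)
  if (kernel == "epanechnikov") h <- h * 1.77
  h
}

#' Kernel utilization distribution on a square grid
#'
#' Estimates the utilization distribution of a set of relocations:
#' `density(cell) = (1/n) * sum_i K_h(cell_center - x_i)` with the bivariate
#' Epanechnikov kernel `K(u) = (2/pi)(1 - u'u)` for `||u|| <= 1` (or the
#' bivariate normal). The grid has `grid_cells` cells per side and covers
#' the point bounding box padded by `extent_factor` times its range on each
#' side; mass is renormalized to 1 over the grid.
#'
#' @param lon,lat Relocation coordinates in degrees (WGS84). Alternatively
#'   `lon` may be a two-column matrix/data.frame of lon/lat.
#' @param grid_cells Cells per grid side (100 or 500 in typical use).
#' @param kernel `"epanechnikov"` (default) or `"bivnorm"`.
#' @param h Bandwidth in metres; default [hrefBandwidth()] on the projected
#'   points.
#' @param extent_factor Padding per side as a fraction of the range (0.5).
#' @return A [UDSurface-class].
#' @export
kernelUD <- function(lon, lat = NULL, grid_cells = 100,
                     kernel = c("epanechnikov", "bivnorm"),
                     h = NULL, extent_factor = 0.5) {
  kernel <- match.arg(kernel)
  if (is.null(lat)) { lat <- lon[, 2]; lon <- lon[, 1] }
  stopifnot(length(lon) == length(lat), length(lon) >= 1)
  lon0 <- mean(lon); lat0 <- mean(lat)
  xy <- projectAEQ(lon, lat, lon0, lat0)
  if (is.null(h)) h <- hrefBandwidth(xy, kernel)
  if (h <= 0) stop("bandwidth must be positive")
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  padx <- max(diff(rx) * extent_factor, h * 2)
  pady <- max(diff(ry) * extent_factor, h * 2)
  width <- max(diff(rx) + 2 * padx, diff(ry) + 2 * pady)
  cs <- width / grid_cells
  cxm <- mean(rx); cym <- mean(ry)
  xmin <- cxm - width / 2; ymin <- cym - width / 2
  xc <- xmin + (seq_len(grid_cells) - 0.5) * cs
  yc <- ymin + (seq_len(grid_cells) - 0.5) * cs
  dens <- matrix(0, grid_cells, grid_cells)  # [ix, iy]
  support <- if (kernel == "epanechnikov") h else 4 * h
  for (i in seq_along(lon)) {
    ix <- which(abs(xc - xy[i, 1]) <= support)
    iy <- which(abs(yc - xy[i, 2]) <= support)
    if (!length(ix) || !length(iy)) next
    du <- outer((xc[ix] - xy[i, 1])^2, (yc[iy] - xy[i, 2])^2, "+") / h^2
    k <- if (kernel == "epanechnikov") {
      v <- (2 / pi) * (1 - du); v[du > 1] <- 0; v
    } else {
      exp(-du / 2) / (2 * pi)
    }
    dens[ix, iy] <- dens[ix, iy] + k / h^2
  }
  total <- sum(dens) * cs^2
  if (total <= 0) stop("all kernel mass fell outside the grid")
  dens <- dens / total
  methods::new("UDSurface", density = dens, xmin = xmin, ymin = ymin,
               cellSize = cs, kernel = kernel, h = h,
               nPoints = length(lon), lon0 = lon0, lat0 = lat0)
}

# rook-adjacency connected components of a set of grid cells
.components <- function(ix, iy) {
  n <- length(ix)
  key <- paste(ix, iy)
  idx <- stats::setNames(seq_len(n), key)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- c(paste(ix[i] + 1, iy[i]), paste(ix[i] - 1, iy[i]),
              paste(ix[i], iy[i] + 1), paste(ix[i], iy[i] - 1))
      hit <- idx[nb]
      hit <- hit[!is.na(hit)]
      hit <- hit[comp[hit] == 0L]
      comp[hit] <- cur
      queue <- c(queue, hit)
    }
  }
  comp
}

#' Volume contour (home range) of a utilization distribution
#'
#' Selects the smallest set of cells whose cumulative descending-density
#' mass reaches `level`; cells of equal density are admitted in
#' deterministic row-major order. The area is the cell count times the cell
#' area, in km^2; selected cells are grouped into rook-adjacent parts.
#'
#' @param ud A [UDSurface-class].
#' @param level Contour level in (0, 1); 0.95 for the home range, 0.50 for
#'   the core area.
#' @param individual,month Optional labels stored on the result.
#' @return A [HomeRange-class].
#' @export
volumeContour <- function(ud, level, individual = NA_character_,
                          month = NA_character_) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  dens <- ud@density
  nx <- nrow(dens); ny <- ncol(dens)
  cellArea <- ud@cellSize^2
  # row-major linear order (iy-major) as deterministic tie-break
  ord <- order(-as.vector(dens), seq_len(nx * ny))
  mass <- cumsum(as.vector(dens)[ord]) * cellArea
  nSel <- which(mass >= level)[1]
  if (is.na(nSel)) nSel <- length(ord)
  sel <- ord[seq_len(nSel)]
  ix <- ((sel - 1) %% nx) + 1
  iy <- ((sel - 1) %/% nx) + 1
  x <- ud@xmin + (ix - 0.5) * ud@cellSize
  y <- ud@ymin + (iy - 0.5) * ud@cellSize
  ll <- unprojectAEQ(x, y, ud@lon0, ud@lat0)
  cells <- data.frame(ix = ix, iy = iy, x = x, y = y,
                      lon = ll[, "lon"], lat = ll[, "lat"],
                      density = dens[cbind(ix, iy)],
                      component = .components(ix, iy))
  methods::new("HomeRange", level = level, cells = cells,
               cellSize = ud@cellSize, xmin = ud@xmin, ymin = ud@ymin,
               gridDim = c(nx, ny), areaKm2 = nSel * cellArea / 1e6,
               lon0 = ud@lon0, lat0 = ud@lat0, kernel = ud@kernel, h = ud@h,
               individual = individual, month = month)
}

#' Split locations by calendar month, excluding partial months
#'
#' Groups one individual's fixes by calendar month. A month is excluded when
#' tracking did not span it fully: the track's first fix is later than the
#' 1st plus `tolerance_days`, or its last fix earlier than the month's end
#' minus `tolerance_days` (so the capture month and the transmitter-failure
#' month drop out).
#'
#' @param tracks Locations of a single individual.
#' @param tolerance_days Partial-month tolerance in days (1).
#' @return `list(months =, excluded =)`: `months` is a named list
#'   (`"YYYY-MM"`) of location subsets; `excluded` a character vector of
#'   month keys that were dropped as partial.
#' @export
monthlySplit <- function(tracks, tolerance_days = 1) {
  stopifnot(length(unique(tracks$individual_id)) <= 1)
  if (!nrow(tracks)) return(list(months = list(), excluded = character()))
  dts <- as.Date(tracks$timestamp)
  key <- format(dts, "%Y-%m")
  first <- min(dts); last <- max(dts)
  months <- sort(unique(key))
  keep <- list(); excluded <- character()
  for (m in months) {
    mStart <- as.Date(paste0(m, "-01"))
    mEnd <- seq(mStart, by = "1 month", length.out = 2)[2] - 1
    if (first > mStart + tolerance_days || last < mEnd - tolerance_days) {
      excluded <- c(excluded, m)
    } else {
      keep[[m]] <- tracks[key == m, , drop = FALSE]
    }
  }
  list(months = keep, excluded = excluded)
}

#' Land-cover composition of a home range
#'
#' Fraction of home-range area per land-cover class, by cell-in-polygon
#' area weighting on the contour's grid cells (all cells have equal area,
#' so fractions are cell-count fractions). Classes under `others_threshold`
#' are flagged for display as "Others"; level-1 aggregates (leading CORINE
#' digit: artificial surfaces, agricultural areas, ...) are also returned.
#'
#' @param hr A [HomeRange-class].
#' @param grid A geographic [asciiGrid()] of CORINE-style class codes.
#' @param others_threshold Display threshold for rare classes (0.01).
#' @return list of class `habitatComposition`: `classes` (data.frame
#'   `code`, `fraction`, `level1`, `others`), `level1` (data.frame `level1`,
#'   `fraction`), `n_cells`.
#' @export
habitatComposition <- function(hr, grid, others_threshold = 0.01) {
  cl <- hr@cells
  codes <- gridLookup(grid, cl$lon, cl$lat, outside = "na")
  if (any(is.na(codes))) {
    i <- which(is.na(codes))[1]
    stop(sprintf(
      "home range extends beyond the land-cover raster near (%.4f, %.4f)",
      cl$lon[i], cl$lat[i]))
  }
  tab <- table(codes)
  frac <- as.numeric(tab) / nrow(cl)
  classes <- data.frame(code = as.integer(names(tab)), fraction = frac)
  classes$level1 <- classes$code %/% 100
  classes$others <- classes$fraction < others_threshold
  lv <- stats::aggregate(fraction ~ level1, classes, sum)
  structure(list(classes = classes, level1 = lv, n_cells = nrow(cl)),
            class = "habitatComposition")
}

#' @export
print.habitatComposition <- function(x, ...) {
  cat("Habitat composition over", x$n_cells, "home-range cells:\n")
  for (i in seq_len(nrow(x$classes)))
    cat(sprintf("  class %d: %5.1f%%%s\n", x$classes$code[i],
                100 * x$classes$fraction[i],
                if (x$classes$others[i]) " (Others)" else ""))
  invisible(x)
}

#' Export a home range as GeoJSON
#'
#' Writes the contour's cells as a MultiPolygon of cell squares in WGS84
#' (one polygon per cell, grouped by part); a lightweight interchange
#' format for GIS overlays, not a dissolved boundary.
#'
#' @param hr A [HomeRange-class].
#' @param path Output path.
#' @export
homeRangeGeoJSON <- function(hr, path) {
  half <- hr@cellSize / 2
  polys <- lapply(seq_len(nrow(hr@cells)), function(i) {
    x <- hr@cells$x[i]; y <- hr@cells$y[i]
    corners <- rbind(c(x - half, y - half), c(x + half, y - half),
                     c(x + half, y + half), c(x - half, y + half),
                     c(x - half, y - half))
    ll <- unprojectAEQ(corners[, 1], corners[, 2], hr@lon0, hr@lat0)
    list(lapply(seq_len(nrow(ll)), function(j) c(ll[j, "lon"], ll[j, "lat"])))
  })
  gj <- list(type = "Feature",
             properties = list(level = hr@level, area_km2 = hr@areaKm2,
                               kernel = hr@kernel, h_m = hr@h,
                               individual = hr@individual, month = hr@month,
                               sphere_radius_m = R_EARTH),
             geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
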