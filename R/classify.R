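#' Classify continuous suitability into four classes
#'
#' Default thresholds: unsuitable `[0, 0.2]`, general `(0.2, 0.4)`,
#' moderate `[0.4, 0.6)`, high `[0.6, 1]`. The 0.2 boundary is unsuitable
#' (the class is defined as "at most 0.2"); the 0.4 and 0.6 boundaries are
#' assigned upward. Nodata propagates.
#'
#' @param suit a [GridLayer-class] with values in `[0, 1]`.
#' @param breaks ascending thresholds `c(unsuitable_max, moderate_min,
#'   high_min)`.
#' @return a [ClassifiedRaster-class] (codes 0-3).
#' @export
classifySuitability <- function(suit, breaks = c(0.2, 0.4, 0.6)) {
  stopifnot(length(breaks) == 3, all(diff(breaks) > 0),
            breaks[1] > 0, breaks[3] < 1)
  v <- suit@values
  codes <- ifelse(v <= breaks[1], 0L,
           ifelse(v < breaks[2], 1L,
           ifelse(v < breaks[3], 2L, 3L)))
  codes[is.na(v)] <- NA_integer_
  new("ClassifiedRaster", grid = suit@grid,
      codes = matrix(as.integer(codes), nrow(v), ncol(v)))
}

#' Per-class areas
#'
#' Sums spherical cell areas (see [cellArea()]) per suitability class.
#'
#' @param classified a [ClassifiedRaster-class].
#' @param unit `"1e4km2"` (default, matching how such areas are usually
#'   tabulated) or `"km2"`.
#' @return data.frame with `class` and `area`, one row per class in code
#'   order (unsuitable, general, moderate, high).
#' @export
classAreas <- function(classified, unit = c("1e4km2", "km2")) {
  unit <- match.arg(unit)
  A <- cellAreaMatrix(classified@grid)
  areas <- vapply(0:3, function(code) {
    sum(A[which(classified@codes == code)])
  }, numeric(1))
  if (unit == "1e4km2") areas <- areas / 1e4
  data.frame(class = suitabilityClasses, area = areas)
}

suitableMask <- function(classified) {
  !is.na(classified@codes) & classified@codes >= 1L
}

#' Gain/loss change map and summary between two periods
#'
#' A cell is "suitable" iff its class is general, moderate or high
#' (suitability > 0.2). `gained` marks cells suitable in the future but
#' not currently; `lost` the converse; `stable` cells suitable in both.
#' `net = gained - lost` exactly. Swapping the arguments swaps gained and
#' lost.
#'
#' @param current,future [ClassifiedRaster-class] objects on one grid.
#' @return list with `gained`, `lost`, `stable` (0/1 [GridLayer-class]
#'   masks) and `summary` (data.frame: `gained`, `lost`, `net` in
#'   10^4 km^2, full precision; round for tabulation).
#' @export
changeMap <- function(current, future) {
  if (!sameGrid(current@grid, future@grid)) {
    stop("current and future rasters are on different grids")
  }
  cur <- suitableMask(current)
  fut <- suitableMask(future)
  A <- cellAreaMatrix(current@grid)
  gained <- fut & !cur
  lost <- cur & !fut
  stable <- cur & fut
  g <- sum(A[gained]) / 1e4
  l <- sum(A[lost]) / 1e4
  mk <- function(mask) {
    m <- matrix(NA_real_, current@grid@nrow, current@grid@ncol)
    ok <- !is.na(current@codes) & !is.na(future@codes)
    m[ok] <- as.numeric(mask[ok])
    gridLayer(current@grid, m)
  }
  list(gained = mk(gained), lost = mk(lost), stable = mk(stable),
       summary = data.frame(gained = g, lost = l, net = g - l))
}

#' Area-weighted centroid of the suitable range
#'
#' Mean cell-center coordinate over suitable cells (class > unsuitable),
#' weighted by spherical cell area — or by `area x suitability` when a
#' suitability layer is supplied for weighting.
#'
#' @param classified a [ClassifiedRaster-class].
#' @param suitability optional [GridLayer-class]; when given, weights are
#'   multiplied by the cell's suitability value.
#' @return data.frame with `longitude`, `latitude`, `n_cells`; when no
#'   cell is suitable, coordinates are `NA` and `n_cells` is 0 (an
#'   explicit "no range" result).
#' @export
rangeCentroid <- function(classified, suitability = NULL) {
  mask <- suitableMask(classified)
  cells <- which(t(mask))   # row-major linear indices
  if (length(cells) == 0L) {
    return(data.frame(longitude = NA_real_, latitude = NA_real_,
                      n_cells = 0L))
  }
  xy <- cellCenter(classified@grid, cells)
  w <- as.vector(t(cellAreaMatrix(classified@grid)))[cells]
  if (!is.null(suitability)) {
    stopifnot(sameGrid(classified@grid, suitability@grid))
    w <- w * as.vector(t(suitability@values))[cells]
  }
  data.frame(
    longitude = sum(w * xy[, "longitude"]) / sum(w),
    latitude = sum(w * xy[, "latitude"]) / sum(w),
    n_cells = length(cells)
  )
}

#' Great-circle shift between two centroids
#'
#' Haversine distance (sphere, R = 6371.0088 km) and initial bearing from
#' `a` to `b`, with the compass octant (N/NE/E/SE/S/SW/W/NW) spanning
#' +/- 22.5 degrees around each cardinal/intercardinal direction. A zero
#' shift reports octant `"none"`.
#'
#' @param a,b centroids: anything with `longitude` and `latitude` fields
#'   (e.g. [rangeCentroid()] output).
#' @return data.frame with `from_longitude`, `from_latitude`,
#'   `to_longitude`, `to_latitude`, `distance_km`, `bearing_deg`,
#'   `octant`.
#' @export
centroidShift <- function(a, b) {
  p1 <- c(a$longitude[1], a$latitude[1])
  p2 <- c(b$longitude[1], b$latitude[1])
  if (anyNA(c(p1, p2))) stop("centroid with no range: cannot compute shift")
  d_km <- geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
  if (d_km == 0) {
    brg <- NA_real_
    octant <- "none"
  } else {
    brg <- (geosphere::bearing(p1, p2) + 360) %% 360
    octants <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
    octant <- octants[floor(((brg + 22.5) %% 360) / 45) + 1]
  }
  data.frame(
    from_longitude = p1[1], from_latitude = p1[2],
    to_longitude = p2[1], to_latitude = p2[2],
    distance_km = d_km, bearing_deg = brg, octant = octant
  )
}

#' Write a classified raster as an ESRI ASCII grid
#'
#' Integer codes 0 (unsuitable) to 3 (high); nodata as the grid sentinel.
#'
#' @param classified a [ClassifiedRaster-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClassified <- function(classified, path) {
  writeAsciiGrid(gridLayer(classified@grid,
                           matrix(as.numeric(classified@codes),
                                  classified@grid@nrow,
                                  classified@grid@ncol)),
                 path)
}
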