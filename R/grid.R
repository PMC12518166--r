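#' @include AllClasses.R
NULL

## Mean Earth radius (IUGG), km — used for all spherical geometry.
EARTH_RADIUS_KM <- 6371.0088

#' Cell indexing on a grid
#'
#' Cells are half-open `[edge, edge + cellsize)` in both axes; matrix row 1
#' is the northernmost row. `cellIndex` returns the linear row-major index
#' `(row - 1) * ncol + col`, or `NA` for points outside the grid.
#'
#' @param grid a [GridSpec-class].
#' @param longitude,latitude point coordinates, decimal degrees.
#' @return `cellRowCol`: a two-column integer matrix (`row`, `col`);
#'   `cellIndex`: an integer vector.
#' @export
cellRowCol <- function(grid, longitude, latitude) {
  col <- floor((longitude - grid@xmin) / grid@cellsize) + 1
  ## rows count from the north: a point just above ymin falls in the last row
  row_s <- floor((latitude - grid@ymin) / grid@cellsize) + 1
  row <- grid@nrow - row_s + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > grid@ncol | row < 1 | row > grid@nrow
  out <- cbind(row = as.integer(row), col = as.integer(col))
  out[bad, ] <- NA_integer_
  out
}

#' @rdname cellRowCol
#' @export
cellIndex <- function(grid, longitude, latitude) {
  rc <- cellRowCol(grid, longitude, latitude)
  as.integer((rc[, "row"] - 1L) * grid@ncol + rc[, "col"])
}

#' Cell-center coordinates
#'
#' @param grid a [GridSpec-class].
#' @param cell linear row-major cell indices.
#' @return two-column matrix (`longitude`, `latitude`) of cell centers.
#' @export
cellCenter <- function(grid, cell) {
  cell <- as.integer(cell)
  row <- (cell - 1L) %/% grid@ncol + 1L
  col <- (cell - 1L) %% grid@ncol + 1L
  lon <- grid@xmin + (col - 0.5) * grid@cellsize
  lat <- grid@ymin + (grid@nrow - row + 0.5) * grid@cellsize
  cbind(longitude = lon, latitude = lat)
}

#' Spherical cell area by grid row
#'
#' Area of one cell in the given row (all cells in a row share a latitude
#' band and hence an area):
#' `R^2 * dlambda * (sin(phi_north) - sin(phi_south))` with
#' `R = 6371.0088` km.
#'
#' @param grid a [GridSpec-class].
#' @param row grid row (1 = northernmost), vectorized.
#' @return cell area(s) in km^2.
#' @export
cellArea <- function(grid, row) {
  phi_n <- (grid@ymin + (grid@nrow - row + 1) * grid@cellsize) * pi / 180
  phi_s <- (grid@ymin + (grid@nrow - row) * grid@cellsize) * pi / 180
  dlam <- grid@cellsize * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(phi_n) - sin(phi_s))
}

#' Per-cell area matrix for a grid
#' @param grid a [GridSpec-class].
#' @return `nrow x ncol` matrix of cell areas in km^2.
#' @export
cellAreaMatrix <- function(grid) {
  matrix(rep(cellArea(grid, seq_len(grid@nrow)), grid@ncol),
         grid@nrow, grid@ncol)
}

sameGrid <- function(a, b, origin_tol = 1e-6, size_tol = 1e-9) {
  a@nrow == b@nrow && a@ncol == b@ncol &&
    abs(a@xmin - b@xmin) <= origin_tol &&
    abs(a@ymin - b@ymin) <= origin_tol &&
    abs(a@cellsize - b@cellsize) <= size_tol
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d rows x %d cols, cell %g deg, lower-left (%g, %g)\n",
    object@nrow, object@ncol, object@cellsize, object@xmin, object@ymin
  ))
})

setMethod("show", "GridLayer", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf(
    "GridLayer on %dx%d grid; %d data cells, range [%g, %g]\n",
    object@grid@nrow, object@grid@ncol, length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA
  ))
})

setMethod("show", "EnvStack", function(object) {
  cat(sprintf(
    "EnvStack '%s': %d layers on %dx%d grid (%s)\n",
    object@scenario, length(object@layers),
    object@grid@nrow, object@grid@ncol,
    paste(names(object@layers), collapse = ", ")
  ))
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet '%s': %d records\n",
              object@species, nrow(object@records)))
})

setMethod("show", "SampleMatrix", function(object) {
  cat(sprintf(
    "SampleMatrix: %d presence + %d background rows, %d variables\n",
    sum(object@label == "presence"), sum(object@label == "background"),
    ncol(object@data)
  ))
})

setMethod("show", "ClassifiedRaster", function(object) {
  tab <- table(factor(object@codes, levels = 0:3, labels = suitabilityClasses))
  cat("ClassifiedRaster:", paste(names(tab), tab, collapse = ", "), "\n")
})

#' Accessors for grid-backed objects
#'
#' `grid()` returns the [GridSpec-class]; `layerNames()` the layer names of
#' an [EnvStack-class]; `getLayer()` one layer as a [GridLayer-class];
#' `values()` the value matrix of a [GridLayer-class]; `records()` the
#' record table of an [OccurrenceSet-class]; `species()` its label.
#'
#' @param x the object.
#' @param name layer name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("grid", function(x) standardGeneric("grid"))
#' @rdname accessors
#' @export
setMethod("grid", "EnvStack", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("grid", "GridLayer", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("grid", "ClassifiedRaster", function(x) x@grid)

#' @rdname accessors
#' @export
layerNames <- function(x) names(x@layers)

#' @rdname accessors
#' @export
getLayer <- function(x, name) {
  stopifnot(is(x, "EnvStack"))
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  gridLayer(x@grid, x@layers[[name]])
}

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setMethod("values", "GridLayer", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "ClassifiedRaster", function(x) x@codes)

#' @rdname accessors
#' @export
records <- function(x) x@records

#' @rdname accessors
#' @export
species <- function(x) x@species
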