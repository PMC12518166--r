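#' @import methods
NULL

#' Geographic grid specification
#'
#' Describes a regular longitude/latitude grid with corner registration:
#' `xmin`/`ymin` are the coordinates of the lower-left *corner*, cells are
#' half-open intervals `[edge, edge + cellsize)`, and the first matrix row is
#' the northernmost row (ESRI ASCII convention). Cell centers sit at
#' `edge + (i + 0.5) * cellsize`.
#'
#' @slot nrow,ncol grid dimensions (rows run north to south).
#' @slot xmin,ymin lower-left corner, decimal degrees (WGS84).
#' @slot cellsize cell edge length in decimal degrees.
#' @slot nodata sentinel value used when writing ESRI ASCII grids; in memory
#'   missing cells are always `NA`.
#'
#' @examples
#' gridSpec(nrow = 10, ncol = 20, xmin = 98, ymin = 28, cellsize = 2.5 / 60)
#' @export
setClass("GridSpec",
  representation(
    nrow = "integer", ncol = "integer",
    xmin = "numeric", ymin = "numeric",
    cellsize = "numeric", nodata = "numeric"
  ),
  prototype(nodata = -9999)
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrow) != 1L || object@nrow < 1L) {
    msg <- c(msg, "nrow must be a single integer >= 1")
  }
  if (length(object@ncol) != 1L || object@ncol < 1L) {
    msg <- c(msg, "ncol must be a single integer >= 1")
  }
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0) {
    msg <- c(msg, "cellsize must be a single positive number")
  }
  if (length(msg) == 0L) {
    xmax <- object@xmin + object@ncol * object@cellsize
    ymax <- object@ymin + object@nrow * object@cellsize
    if (object@xmin < -180 - 1e-9 || xmax > 180 + 1e-9) {
      msg <- c(msg, "grid longitudes must lie within [-180, 180]")
    }
    if (object@ymin < -90 - 1e-9 || ymax > 90 + 1e-9) {
      msg <- c(msg, "grid latitudes must lie within [-90, 90]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [GridSpec-class]
#'
#' @param nrow,ncol grid dimensions.
#' @param xmin,ymin lower-left corner in decimal degrees.
#' @param cellsize cell size in decimal degrees.
#' @param nodata sentinel used on ESRI ASCII output.
#' @return a `GridSpec` object.
#' @export
gridSpec <- function(nrow, ncol, xmin, ymin, cellsize, nodata = -9999) {
  new("GridSpec",
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    cellsize = as.numeric(cellsize), nodata = as.numeric(nodata)
  )
}

#' Single raster layer on a [GridSpec-class]
#'
#' Values are stored as an `nrow x ncol` matrix with row 1 = northernmost
#' row; `NA` marks nodata.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric matrix of cell values.
#' @export
setClass("GridLayer",
  representation(grid = "GridSpec", values = "matrix")
)

setValidity("GridLayer", function(object) {
  d <- dim(object@values)
  if (d[1] != object@grid@nrow || d[2] != object@grid@ncol) {
    return("values matrix does not match grid dimensions")
  }
  TRUE
})

#' Construct a [GridLayer-class]
#' @param grid a [GridSpec-class].
#' @param values numeric matrix (`nrow x ncol`, row 1 north) or a single
#'   number recycled over the grid.
#' @return a `GridLayer`.
#' @export
gridLayer <- function(grid, values) {
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), grid@nrow, grid@ncol)
  }
  new("GridLayer", grid = grid, values = values)
}

#' Aligned stack of named environmental layers
#'
#' All layers share one [GridSpec-class] and one nodata mask (the union of
#' the individual layer masks is applied to every layer on construction).
#'
#' @slot grid a [GridSpec-class].
#' @slot layers named list of numeric matrices, one per variable.
#' @slot scenario free-text label ("current", "SSP585 2061-2080", ...).
#' @export
setClass("EnvStack",
  representation(grid = "GridSpec", layers = "list", scenario = "character"),
  prototype(scenario = "current")
)

setValidity("EnvStack", function(object) {
  msg <- character()
  nm <- names(object@layers)
  if (length(object@layers) < 1L) msg <- c(msg, "stack needs >= 1 layer")
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    msg <- c(msg, "layer names must be unique and non-empty")
  }
  for (i in seq_along(object@layers)) {
    d <- dim(object@layers[[i]])
    if (is.null(d) || d[1] != object@grid@nrow || d[2] != object@grid@ncol) {
      msg <- c(msg, sprintf("layer '%s' does not match grid dimensions", nm[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an [EnvStack-class]
#'
#' @param grid a [GridSpec-class].
#' @param layers named list of matrices (`nrow x ncol`, row 1 north).
#' @param scenario scenario label.
#' @return an `EnvStack` with the union nodata mask applied to all layers.
#' @export
envStack <- function(grid, layers, scenario = "current") {
  mask <- Reduce(`|`, lapply(layers, is.na))
  if (any(mask)) layers <- lapply(layers, function(m) { m[mask] <- NA; m })
  new("EnvStack", grid = grid, layers = layers, scenario = scenario)
}

#' Georeferenced presence records for one species
#'
#' @slot species species label shared by all records.
#' @slot records data.frame with columns `species`, `longitude`, `latitude`,
#'   `elevation` (m, may be `NA`) and `year` (may be `NA`).
#' @export
setClass("OccurrenceSet",
  representation(species = "character", records = "data.frame")
)

setValidity("OccurrenceSet", function(object) {
  msg <- character()
  need <- c("species", "longitude", "latitude", "elevation", "year")
  if (!all(need %in% names(object@records))) {
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  } else {
    r <- object@records
    if (nrow(r) > 0L) {
      if (!all(r$species == object@species)) {
        msg <- c(msg, "all records must share the set's species label")
      }
      bad_lon <- !is.na(r$longitude) & (r$longitude < -180 | r$longitude > 180)
      bad_lat <- !is.na(r$latitude) & (r$latitude < -90 | r$latitude > 90)
      if (any(bad_lon) || any(bad_lat)) {
        msg <- c(msg, "coordinates outside [-180,180] x [-90,90]")
      }
      bad_year <- !is.na(r$year) & (r$year < 1800 | r$year > 2100)
      if (any(bad_year)) msg <- c(msg, "years must lie in [1800, 2100]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an [OccurrenceSet-class]
#' @param species species label.
#' @param records data.frame; missing `elevation`/`year` columns are added
#'   as `NA`.
#' @return an `OccurrenceSet`.
#' @export
occurrenceSet <- function(species, records) {
  records <- as.data.frame(records)
  if (!"species" %in% names(records)) records$species <- species
  for (col in c("elevation", "year")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  keep <- c("species", "longitude", "latitude", "elevation", "year")
  extra <- setdiff(names(records), keep)
  new("OccurrenceSet", species = species,
      records = records[, c(keep, extra), drop = FALSE])
}

#' Presence/background design matrix
#'
#' Rows are sampled landscape cells; columns are environmental variables.
#' `label` marks each row `"presence"` or `"background"`; `cell` is the
#' linear landscape cell index (row-major from the north-west corner),
#' used to deduplicate the model landscape.
#'
#' @slot data numeric matrix, no `NA`s, named columns.
#' @slot label character vector, one of `"presence"`, `"background"`.
#' @slot cell integer cell indices (`NA` allowed for free-standing points).
#' @slot grid the [GridSpec-class] the cells refer to.
#' @export
setClass("SampleMatrix",
  representation(data = "matrix", label = "character", cell = "integer",
                 grid = "GridSpec")
)

setValidity("SampleMatrix", function(object) {
  msg <- character()
  n <- nrow(object@data)
  if (anyNA(object@data)) msg <- c(msg, "data must not contain NA")
  if (is.null(colnames(object@data))) msg <- c(msg, "data needs column names")
  if (length(object@label) != n || length(object@cell) != n) {
    msg <- c(msg, "label and cell must have one entry per row")
  }
  if (!all(object@label %in% c("presence", "background"))) {
    msg <- c(msg, "labels must be 'presence' or 'background'")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted maximum-entropy presence-background model
#'
#' Stores everything needed to re-project without refitting: the feature
#' definitions with their raw-unit knots, per-variable scaling bounds, the
#' L1-penalized feature weights, the training-landscape log-normalizer and
#' the entropy of the fitted raw distribution.
#'
#' @slot features data.frame with columns `kind` (linear/quadratic/product/
#'   hinge/threshold), `var1`, `var2`, `knot` (raw units) and `direction`
#'   (`"forward"`/`"reverse"`, hinge only).
#' @slot bounds 2-row matrix (`min`, `max`) of training bounds per variable.
#' @slot lambdas numeric feature weights.
#' @slot beta numeric effective L1 penalty per feature.
#' @slot fc feature-class label (`"L"`, `"LQ"`, `"H"`, `"LQH"`, `"LQHP"`,
#'   `"LQHPT"`).
#' @slot rm regularization multiplier.
#' @slot logZ log-normalizer of the raw distribution over the training
#'   landscape.
#' @slot entropy entropy (nats) of the fitted raw distribution.
#' @slot gain final regularized training gain (nats, relative to uniform).
#' @slot varGain named per-variable gain credits accrued along the
#'   optimization path (basis of percent contribution).
#' @slot presenceMeans named means of the raw variables over presence rows
#'   (used for marginal response curves).
#' @slot nPresence,nLandscape presence count and deduplicated landscape size.
#' @slot iterations number of coordinate-descent sweeps run.
#' @slot converged logical.
#' @export
setClass("MaxentModel",
  representation(
    features = "data.frame", bounds = "matrix", lambdas = "numeric",
    beta = "numeric", fc = "character", rm = "numeric",
    logZ = "numeric", entropy = "numeric", gain = "numeric",
    varGain = "numeric", presenceMeans = "numeric",
    nPresence = "integer", nLandscape = "integer",
    iterations = "integer", converged = "logical"
  )
)

setValidity("MaxentModel", function(object) {
  msg <- character()
  if (length(object@lambdas) != nrow(object@features)) {
    msg <- c(msg, "one lambda per feature required")
  }
  if (length(object@entropy) == 1L && is.finite(object@entropy) &&
      object@entropy > log(object@nLandscape) + 1e-6) {
    msg <- c(msg, "entropy cannot exceed log(#landscape cells)")
  }
  if (length(msg)) msg else TRUE
})

#' Four-class suitability raster
#'
#' Integer codes: 0 unsuitable, 1 general, 2 moderate, 3 high; `NA` nodata.
#'
#' @slot grid a [GridSpec-class].
#' @slot codes integer matrix of class codes.
#' @export
setClass("ClassifiedRaster",
  representation(grid = "GridSpec", codes = "matrix")
)

setValidity("ClassifiedRaster", function(object) {
  d <- dim(object@codes)
  if (d[1] != object@grid@nrow || d[2] != object@grid@ncol) {
    return("codes matrix does not match grid dimensions")
  }
  v <- object@codes[!is.na(object@codes)]
  if (length(v) && !all(v %in% 0:3)) {
    return("codes must be in 0:3 (unsuitable/general/moderate/high)")
  }
  TRUE
})

#' Class labels used by [classifySuitability()]
#' @export
suitabilityClasses <- c("unsuitable", "general", "moderate", "high")
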