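#' Extract environmental values at occurrence points
#'
#' Each point takes the value of the cell containing it (half-open cells
#' `[edge, edge + cellsize)`). Points outside the grid are an error;
#' points falling in nodata cells are dropped and reported.
#'
#' @param stack an [EnvStack-class].
#' @param points an [OccurrenceSet-class].
#' @return a presence [SampleMatrix-class]; `attr(x, "dropped_nodata")`
#'   lists record indices dropped for nodata.
#' @export
extractSamples <- function(stack, points) {
  r <- points@records
  cell <- cellIndex(stack@grid, r$longitude, r$latitude)
  if (anyNA(cell)) {
    stop("points outside grid extent at records: ",
         paste(which(is.na(cell)), collapse = ", "))
  }
  X <- stackMatrix(stack)[cell, , drop = FALSE]
  bad <- which(rowSums(is.na(X)) > 0)
  keep <- setdiff(seq_along(cell), bad)
  out <- new("SampleMatrix",
    data = X[keep, , drop = FALSE],
    label = rep("presence", length(keep)),
    cell = cell[keep], grid = stack@grid
  )
  attr(out, "dropped_nodata") <- bad
  out
}

## All layers as an (ncell x nlayer) matrix in row-major cell order.
stackMatrix <- function(stack) {
  do.call(cbind, lapply(stack@layers, function(m) as.vector(t(m))))
}

#' Draw background cells uniformly without replacement
#'
#' @param stack an [EnvStack-class].
#' @param n number of background cells; must not exceed the number of data
#'   cells (after `exclude`).
#' @param seed integer seed.
#' @param exclude optional integer vector of cell indices to exclude.
#' @return a background [SampleMatrix-class].
#' @export
sampleBackground <- function(stack, n = 10000, seed, exclude = NULL) {
  X <- stackMatrix(stack)
  avail <- which(rowSums(is.na(X)) == 0)
  if (!is.null(exclude)) avail <- setdiff(avail, exclude)
  if (n > length(avail)) {
    stop(sprintf("requested %d background cells but only %d available",
                 n, length(avail)))
  }
  set.seed(as.integer(seed))
  cells <- sort(sample(avail, n, replace = FALSE))
  new("SampleMatrix",
    data = X[cells, , drop = FALSE],
    label = rep("background", n),
    cell = as.integer(cells), grid = stack@grid
  )
}

#' Combine presence and background rows
#'
#' @param ... [SampleMatrix-class] objects on the same grid with the same
#'   variables.
#' @return a single [SampleMatrix-class].
#' @export
bindSamples <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(colnames(p@data), colnames(ref@data))) {
      stop("sample matrices have different variables")
    }
    if (!sameGrid(p@grid, ref@grid)) stop("sample matrices on different grids")
  }
  new("SampleMatrix",
    data = do.call(rbind, lapply(parts, methods::slot, "data")),
    label = unlist(lapply(parts, methods::slot, "label")),
    cell = unlist(lapply(parts, methods::slot, "cell")),
    grid = ref@grid
  )
}

#' Restrict a sample matrix to a subset of variables
#' @param sm a [SampleMatrix-class].
#' @param vars variable names to keep.
#' @return a [SampleMatrix-class].
#' @export
selectColumns <- function(sm, vars) {
  miss <- setdiff(vars, colnames(sm@data))
  if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "))
  new("SampleMatrix", data = sm@data[, vars, drop = FALSE],
      label = sm@label, cell = sm@cell, grid = sm@grid)
}

subsetRows <- function(sm, idx) {
  new("SampleMatrix", data = sm@data[idx, , drop = FALSE],
      label = sm@label[idx], cell = sm@cell[idx], grid = sm@grid)
}
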