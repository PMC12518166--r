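#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (keys case-insensitive: `NCOLS`,
#' `NROWS`, `XLLCORNER`/`XLLCENTER`, `YLLCORNER`/`YLLCENTER`, `CELLSIZE`,
#' optional `NODATA_VALUE`, default -9999) followed by `NROWS` lines of
#' values, first line = northernmost row. Center registration is normalized
#' to corner registration (`corner = center - cellsize / 2`). Cells equal to
#' the nodata value become `NA`.
#'
#' @param path file path.
#' @return a [GridLayer-class].
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                   "yllcorner", "yllcenter", "cellsize", "nodata_value")) {
      if (length(parts) != 2L) stop("malformed header line: ", lines[i])
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val)) stop("non-numeric header value in: ", lines[i])
      hdr[[key]] <- val
      body_start <- i + 1L
    } else {
      break
    }
  }
  for (need in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[need]])) stop("header missing required key: ", need)
  }
  if (hdr$cellsize <= 0) stop("inconsistent header: cellsize must be > 0")
  if (!is.null(hdr$xllcorner) && !is.null(hdr$xllcenter)) {
    stop("inconsistent header: both XLLCORNER and XLLCENTER present")
  }
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
          else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
          else stop("header missing XLLCORNER/XLLCENTER")
  ymin <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
          else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
          else stop("header missing YLLCORNER/YLLCENTER")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999

  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[seq(body_start, length(lines))]), "\\s+")
  )))
  n_expect <- hdr$ncols * hdr$nrows
  if (anyNA(vals)) stop("non-numeric value in grid body")
  if (length(vals) != n_expect) {
    stop(sprintf("truncated or overlong body: expected %d values, got %d",
                 n_expect, length(vals)))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  spec <- gridSpec(hdr$nrows, hdr$ncols, xmin, ymin, hdr$cellsize, nodata)
  gridLayer(spec, m)
}

#' Write an ESRI ASCII grid
#'
#' Writes corner-registered headers and one line per grid row (north
#' first); `NA` cells are written as the grid's nodata sentinel. Values are
#' printed with enough digits that a read/write round trip preserves them.
#'
#' @param layer a [GridLayer-class] (or use `grid` + `values`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path) {
  g <- layer@grid
  m <- layer@values
  m[is.na(m)] <- g@nodata
  hdr <- c(
    sprintf("NCOLS %d", g@ncol),
    sprintf("NROWS %d", g@nrow),
    sprintf("XLLCORNER %.10g", g@xmin),
    sprintf("YLLCORNER %.10g", g@ymin),
    sprintf("CELLSIZE %.12g", g@cellsize),
    sprintf("NODATA_VALUE %.10g", g@nodata)
  )
  rows <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read aligned ASCII grids into an [EnvStack-class]
#'
#' All layers must share one grid: identical dimensions, origin within
#' 1e-6 degrees and cell size within 1e-9 degrees; a mismatch error names
#' the offending layer and field. The union nodata mask is applied to every
#' layer.
#'
#' @param paths named character vector or list, layer name -> `.asc` path.
#' @param scenario scenario label for the stack.
#' @return an [EnvStack-class].
#' @export
buildStack <- function(paths, scenario = "current") {
  if (length(paths) < 1L) stop("need at least one layer")
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("paths must be named by layer")
  }
  layers <- lapply(paths, readAsciiGrid)
  ref <- layers[[1]]@grid
  for (i in seq_along(layers)[-1]) {
    g <- layers[[i]]@grid
    nm <- names(paths)[i]
    if (g@nrow != ref@nrow || g@ncol != ref@ncol) {
      stop(sprintf("layer '%s': dimensions %dx%d differ from %dx%d",
                   nm, g@nrow, g@ncol, ref@nrow, ref@ncol))
    }
    if (abs(g@xmin - ref@xmin) > 1e-6 || abs(g@ymin - ref@ymin) > 1e-6) {
      stop(sprintf("layer '%s': origin (%g, %g) differs from (%g, %g)",
                   nm, g@xmin, g@ymin, ref@xmin, ref@ymin))
    }
    if (abs(g@cellsize - ref@cellsize) > 1e-9) {
      stop(sprintf("layer '%s': cellsize %g differs from %g",
                   nm, g@cellsize, ref@cellsize))
    }
  }
  envStack(ref, lapply(layers, methods::slot, "values"), scenario = scenario)
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' @param stack an [EnvStack-class].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack@layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    writeAsciiGrid(gridLayer(stack@grid, stack@layers[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}
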