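#' Read occurrence records from CSV
#'
#' Expects columns `species`, `longitude`, `latitude` and optionally
#' `elevation` and `year`. Rows for other species are ignored. Malformed
#' rows (unparseable or out-of-range coordinates, impossible years) are
#' excluded and reported row-by-row in the `"problems"` attribute rather
#' than dropped silently.
#'
#' @param path CSV file.
#' @param species species label to extract.
#' @return an [OccurrenceSet-class]; `attr(x, "problems")` is a data.frame
#'   (`row`, `reason`) of excluded rows.
#' @export
readOccurrences <- function(path, species) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in c("elevation", "year")) {
    if (!col %in% names(raw)) raw[[col]] <- rep(NA_character_, nrow(raw))
  }
  rows <- which(raw$species == species)
  num <- function(x) suppressWarnings(as.numeric(x))
  lon <- num(raw$longitude[rows]); lat <- num(raw$latitude[rows])
  elev <- num(raw$elevation[rows]); year <- num(raw$year[rows])
  blank <- function(x) is.na(x) & nzchar(trimws(ifelse(is.na(x), "", x)))

  reason <- rep(NA_character_, length(rows))
  src_lon <- raw$longitude[rows]; src_lat <- raw$latitude[rows]
  reason[is.na(lon) & nzchar(trimws(src_lon))] <- "unparseable longitude"
  reason[is.na(lat) & nzchar(trimws(src_lat))] <- "unparseable latitude"
  reason[!is.na(lon) & (lon < -180 | lon > 180)] <- "longitude out of range"
  reason[!is.na(lat) & (lat < -90 | lat > 90)] <- "latitude out of range"
  reason[!is.na(year) & (year < 1800 | year > 2100)] <- "year out of range"

  bad <- !is.na(reason)
  problems <- data.frame(row = rows[bad], reason = reason[bad])
  keep <- !bad
  recs <- data.frame(
    species = rep(species, sum(keep)), longitude = lon[keep],
    latitude = lat[keep], elevation = elev[keep], year = year[keep]
  )
  out <- occurrenceSet(species, recs)
  attr(out, "problems") <- problems
  out
}

#' Drop duplicates and coordinate-less records
#'
#' Exact duplicate (longitude, latitude) pairs collapse to the first
#' record; records missing either coordinate are dropped; all other order
#' is preserved. Idempotent.
#'
#' @param set an [OccurrenceSet-class].
#' @return a cleaned [OccurrenceSet-class]; `attr(x, "n_dropped")` counts
#'   removed records.
#' @export
cleanOccurrences <- function(set) {
  r <- set@records
  has_xy <- !is.na(r$longitude) & !is.na(r$latitude)
  r <- r[has_xy, , drop = FALSE]
  dup <- duplicated(r[, c("longitude", "latitude")])
  r <- r[!dup, , drop = FALSE]
  out <- occurrenceSet(set@species, r)
  attr(out, "n_dropped") <- nrow(set@records) - nrow(r)
  out
}

#' Spatially thin to one record per grid cell
#'
#' Assigns each record to its grid cell (`floor((coord - edge)/cellsize)`,
#' the same half-open convention the raster stage uses) and keeps one
#' record per occupied cell, chosen uniformly at random under the seed.
#' Thinning an already-thinned set is a no-op. Records outside the grid are
#' an error listing the offending rows.
#'
#' @param set an [OccurrenceSet-class].
#' @param grid a [GridSpec-class] (typically the environmental grid).
#' @param seed integer seed for within-cell retention.
#' @return thinned [OccurrenceSet-class]; `attr(x, "report")` is a list
#'   with `n_input`, `n_retained`, `n_dropped`, `cells_occupied` and
#'   `seed`.
#' @export
thinOccurrences <- function(set, grid, seed) {
  r <- set@records
  if (nrow(r) == 0L) {
    out <- set
    attr(out, "report") <- list(species = set@species, n_input = 0L,
                                n_retained = 0L, n_dropped = 0L,
                                cells_occupied = 0L, seed = seed)
    return(out)
  }
  cell <- cellIndex(grid, r$longitude, r$latitude)
  if (anyNA(cell)) {
    stop("records outside grid extent at rows: ",
         paste(which(is.na(cell)), collapse = ", "))
  }
  set.seed(as.integer(seed))
  ## sample one row index per occupied cell, uniform within cell
  perm <- sample.int(nrow(r))
  keep <- perm[!duplicated(cell[perm])]
  keep <- sort(keep)
  out <- occurrenceSet(set@species, r[keep, , drop = FALSE])
  attr(out, "report") <- list(
    species = set@species, n_input = nrow(r), n_retained = length(keep),
    n_dropped = nrow(r) - length(keep),
    cells_occupied = length(unique(cell)), seed = seed
  )
  out
}

#' Aggregate thinning reports across species
#'
#' @param sets list of thinned [OccurrenceSet-class] objects (as returned
#'   by [thinOccurrences()]).
#' @return data.frame, one row per species plus a `"total"` row, with
#'   `n_input`, `n_retained` and `n_dropped`.
#' @export
thinningSummary <- function(sets) {
  rows <- lapply(sets, function(s) {
    rep <- attr(s, "report")
    if (is.null(rep)) {
      rep <- list(species = s@species, n_input = NA_integer_,
                  n_retained = nrow(s@records), n_dropped = NA_integer_)
    }
    data.frame(species = rep$species, n_input = rep$n_input,
               n_retained = rep$n_retained, n_dropped = rep$n_dropped)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(
    species = "total", n_input = sum(out$n_input),
    n_retained = sum(out$n_retained), n_dropped = sum(out$n_dropped)
  ))
}
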