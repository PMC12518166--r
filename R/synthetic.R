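#' Synthetic landscapes with known ground truth
#'
#' The generator builds seeded, spatially autocorrelated environmental
#' stacks, a logistic true-suitability surface, presence samples drawn
#' proportional to that surface, and future scenarios as additive shifts —
#' so every downstream stage of the pipeline can be exercised against a
#' known answer.
#'
#' @name synthetic-world
NULL

## Spatially autocorrelated field: seeded white noise smoothed with a
## separable Gaussian kernel (reflection padding), re-standardized to
## mean 0 / sd 1 so noise_sd has its nominal meaning after smoothing.
smoothNoise <- function(nrow, ncol, sigma) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    reflect <- function(idx, n) {
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      ifelse(idx > n, 2L * n - idx, idx)
    }
    conv1 <- function(m, along_rows) {
      n <- if (along_rows) nrow(m) else ncol(m)
      out <- 0
      for (o in seq(-half, half)) {
        idx <- reflect(seq_len(n) + o, n)
        out <- out + k[o + half + 1L] *
          (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
      }
      out
    }
    z <- conv1(conv1(z, TRUE), FALSE)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Describe one synthetic layer
#'
#' @param name layer name (e.g. `"elev"`, `"bio11"`).
#' @param trend deterministic spatial trend: `"flat"`, `"ns"` (increasing
#'   northwards), `"ew"` (increasing eastwards), `"ridge"` (north-south
#'   Gaussian ridge) or `"radial"` (central bump).
#' @param trend_range numeric `c(lo, hi)`: layer units spanned by the trend.
#' @param noise_sd standard deviation of the additive smoothed-noise field,
#'   in layer units.
#' @param smooth_sigma Gaussian smoothing radius of the noise, in cells.
#' @param cor_elev if non-`NULL`, the layer is instead constructed to have
#'   exactly this empirical Pearson correlation with the stack's `"elev"`
#'   layer (which must come earlier in the recipe); `mean` and `sd` then
#'   set its units.
#' @param mean,sd mean and standard deviation used with `cor_elev`.
#' @return a recipe entry (list) for [makeStack()].
#' @export
layerRecipe <- function(name, trend = "flat", trend_range = c(0, 1),
                        noise_sd = 0, smooth_sigma = 2, cor_elev = NULL,
                        mean = 0, sd = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            trend %in% c("flat", "ns", "ew", "ridge", "radial"))
  if (!is.null(cor_elev)) stopifnot(abs(cor_elev) <= 1)
  list(name = name, trend = trend, trend_range = trend_range,
       noise_sd = noise_sd, smooth_sigma = smooth_sigma,
       cor_elev = cor_elev, mean = mean, sd = sd)
}

#' Generate a synthetic environmental stack
#'
#' Layers are built in recipe order as deterministic trend + smoothed
#' seeded noise; entries with `cor_elev` are mixed from the standardized
#' elevation field and an elevation-orthogonalized noise field so the
#' requested correlation is attained exactly on the generated cells. The
#' same seed always reproduces the same stack bit-for-bit.
#'
#' @param spec a [GridSpec-class].
#' @param recipe list of [layerRecipe()] entries with unique names.
#' @param seed integer seed.
#' @return an [EnvStack-class] (scenario `"current"`).
#' @export
makeStack <- function(spec, recipe, seed) {
  if (length(recipe) == 0L) stop("empty recipe")
  nms <- vapply(recipe, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate layer name: ", nms[duplicated(nms)][1])
  }
  set.seed(as.integer(seed))
  nr <- spec@nrow; nc <- spec@ncol
  trend_field <- function(kind) {
    switch(kind,
      flat = matrix(0.5, nr, nc),
      ns = matrix(rep((nr - seq_len(nr) + 0.5) / nr, nc), nr, nc),
      ew = matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc),
      ridge = {
        d <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - (nc + 1) / 2)
        exp(-d^2 / (2 * (nc / 5)^2))
      },
      radial = {
        dr <- matrix(rep(seq_len(nr), nc), nr, nc) - (nr + 1) / 2
        dc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - (nc + 1) / 2
        exp(-(dr^2 + dc^2) / (2 * (min(nr, nc) / 5)^2))
      }
    )
  }
  layers <- list()
  for (r in recipe) {
    if (!is.null(r$cor_elev)) {
      if (!"elev" %in% names(layers)) {
        stop("cor_elev requires an earlier 'elev' layer in the recipe")
      }
      ze <- as.vector(layers[["elev"]])
      ze <- (ze - mean(ze)) / stats::sd(ze)
      noise <- as.vector(smoothNoise(nr, nc, r$smooth_sigma))
      res <- stats::residuals(stats::lm(noise ~ ze))
      zr <- (res - mean(res)) / stats::sd(res)
      z <- r$cor_elev * ze + sqrt(1 - r$cor_elev^2) * zr
      z <- (z - mean(z)) / stats::sd(z)
      layers[[r$name]] <- matrix(r$mean + r$sd * z, nr, nc)
    } else {
      t <- trend_field(r$trend)
      v <- r$trend_range[1] + diff(r$trend_range) * t
      if (r$noise_sd > 0) {
        v <- v + r$noise_sd * smoothNoise(nr, nc, r$smooth_sigma)
      }
      layers[[r$name]] <- v
    }
  }
  envStack(spec, layers, scenario = "current")
}

#' Default synthetic-world recipe
#'
#' A montane landscape at 2.5-arc-minute style resolution: a north-south
#' elevation ridge (1500-4500 m), a coldest-quarter temperature layer
#' strongly anti-correlated with elevation, a northwards precipitation
#' gradient, a temperature-seasonality layer loosely tied to elevation, a
#' human-footprint field and a pure-noise layer with no ecological signal.
#'
#' @return list of [layerRecipe()] entries.
#' @export
defaultRecipe <- function() {
  list(
    layerRecipe("elev", trend = "ridge", trend_range = c(1500, 4500),
                noise_sd = 300, smooth_sigma = 3),
    layerRecipe("bio11", cor_elev = -0.9, mean = 2, sd = 4,
                smooth_sigma = 3),
    layerRecipe("bio12", trend = "ns", trend_range = c(400, 1200),
                noise_sd = 120, smooth_sigma = 3),
    layerRecipe("bio4", cor_elev = -0.4, mean = 700, sd = 120,
                smooth_sigma = 3),
    layerRecipe("hfp", trend = "flat", trend_range = c(0, 30),
                noise_sd = 8, smooth_sigma = 2),
    layerRecipe("noise01", trend = "flat", noise_sd = 1, smooth_sigma = 0)
  )
}

#' Known true response surface
#'
#' The ground-truth suitability is the inverse logit of a linear/quadratic
#' form in standardized layers. A variable listed in `optimum` contributes
#' `-|coef| * ((x - opt) / sd(x))^2` (maximal at `opt`); other coefficients
#' contribute `coef * (x - mean(x)) / sd(x)`.
#'
#' @param intercept intercept on the logit scale.
#' @param coefficients named numeric, layer name -> weight per standardized
#'   unit.
#' @param optimum named numeric, layer name -> value (layer units) at which
#'   true suitability peaks for that variable.
#' @return a `trueModel` list.
#' @export
trueModel <- function(intercept = 0, coefficients = numeric(0),
                      optimum = numeric(0)) {
  stopifnot(is.numeric(coefficients), is.numeric(optimum))
  if (length(optimum) && !all(names(optimum) %in% names(coefficients))) {
    stop("every optimum variable needs a coefficient")
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 optimum = optimum), class = "trueModel")
}

#' Evaluate the true suitability surface
#'
#' @param stack an [EnvStack-class].
#' @param model a [trueModel()].
#' @return a [GridLayer-class] with values in (0, 1); nodata propagated.
#' @export
trueSuitability <- function(stack, model) {
  miss <- setdiff(names(model$coefficients), names(stack@layers))
  if (length(miss)) stop("coefficient layers missing from stack: ",
                         paste(miss, collapse = ", "))
  eta <- matrix(model$intercept, stack@grid@nrow, stack@grid@ncol)
  for (nm in names(model$coefficients)) {
    x <- stack@layers[[nm]]
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    cf <- model$coefficients[[nm]]
    if (nm %in% names(model$optimum)) {
      eta <- eta - abs(cf) * ((x - model$optimum[[nm]]) / s)^2
    } else {
      eta <- eta + cf * (x - mu) / s
    }
  }
  gridLayer(stack@grid, stats::plogis(eta))
}

#' Sample presence records proportional to suitability
#'
#' Draws `n` records (with replacement, multinomially) over data cells with
#' probability proportional to suitability times the optional bias layer;
#' records are placed at cell centers. If `stack` holds an `"elev"` layer
#' its value is attached; collection years are drawn uniformly over
#' `year_range`, or, when `year_elev_link > 0`, with a rank correlation
#' between elevation and year so the elevation-trend stage has signal.
#'
#' @param suit a [GridLayer-class] of suitabilities.
#' @param n number of records.
#' @param seed integer seed.
#' @param bias optional [GridLayer-class] sampling-bias weights.
#' @param stack optional [EnvStack-class] to source elevations from.
#' @param species species label.
#' @param year_range integer `c(first, last)` collection years.
#' @param year_elev_link in `[0, 1]`: strength of the elevation-year link.
#' @return an [OccurrenceSet-class].
#' @export
sampleOccurrences <- function(suit, n, seed, bias = NULL, stack = NULL,
                              species = "synthetic",
                              year_range = c(1950, 2020),
                              year_elev_link = 0) {
  stopifnot(n >= 1)
  p <- as.vector(t(suit@values))          # row-major cell order
  if (!is.null(bias)) {
    stopifnot(sameGrid(suit@grid, bias@grid))
    p <- p * as.vector(t(bias@values))
  }
  ok <- which(!is.na(p) & p > 0)
  if (length(ok) == 0L) stop("no data cell with positive sampling weight")
  set.seed(as.integer(seed))
  cells <- ok[sample.int(length(ok), n, replace = TRUE, prob = p[ok])]
  xy <- cellCenter(suit@grid, cells)
  elev <- rep(NA_real_, n)
  if (!is.null(stack) && "elev" %in% names(stack@layers)) {
    ev <- as.vector(t(stack@layers[["elev"]]))
    elev <- ev[cells]
  }
  if (year_elev_link > 0 && !all(is.na(elev))) {
    z <- (elev - mean(elev)) / max(stats::sd(elev), 1e-12)
    u <- year_elev_link * z + sqrt(1 - year_elev_link^2) * stats::rnorm(n)
    year <- round(year_range[1] + diff(year_range) * stats::pnorm(u))
  } else {
    year <- sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
  }
  occurrenceSet(species, data.frame(
    species = species, longitude = xy[, "longitude"],
    latitude = xy[, "latitude"], elevation = elev, year = year
  ))
}

#' Derive a future scenario stack by additive shifts
#'
#' Named layers are shifted cellwise by their delta; all other layers
#' (elevation, soil, human footprint, ...) are carried over bit-identical,
#' mirroring the static-human-footprint assumption of scenario projection.
#' Nodata cells stay nodata.
#'
#' @param stack an [EnvStack-class].
#' @param scenario label for the derived stack (e.g. `"SSP585 2061-2080"`).
#' @param deltas named numeric, layer name -> additive shift in layer units.
#' @return a shifted [EnvStack-class].
#' @export
makeFuture <- function(stack, scenario, deltas = numeric(0)) {
  bad <- setdiff(names(deltas), names(stack@layers))
  if (length(bad)) stop("deltas name unknown layers: ",
                        paste(bad, collapse = ", "))
  layers <- stack@layers
  for (nm in names(deltas)) layers[[nm]] <- layers[[nm]] + deltas[[nm]]
  new("EnvStack", grid = stack@grid, layers = layers, scenario = scenario)
}

#' Write occurrence records as CSV
#'
#' Columns: `species,longitude,latitude,elevation,year`.
#'
#' @param occ an [OccurrenceSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(
    occ@records[, c("species", "longitude", "latitude", "elevation", "year")],
    path, row.names = FALSE
  )
  invisible(path)
}
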