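#' Assemble a run configuration
#'
#' Collects every setting of the study pipeline in one list, with every
#' default surfaced. Stacks and occurrence sets may be given either as
#' in-memory objects ([EnvStack-class], [OccurrenceSet-class]) or as
#' paths (named `.asc` layer paths / a CSV file), so the same entry point
#' drives synthetic and file-based runs.
#'
#' @param species list of entries `list(name = , occurrences = )` where
#'   `occurrences` is a CSV path or an [OccurrenceSet-class].
#' @param current the current-climate stack: [EnvStack-class] or named
#'   `.asc` paths.
#' @param scenarios list of entries `list(label = , group = , stack = )`;
#'   `group` chains periods of one emissions pathway in order, so the
#'   second period's "distance 2" is measured from the first period's
#'   centroid.
#' @param background_size background sample size (capped at the number of
#'   data cells).
#' @param fcs,rms tuning grids.
#' @param hinge_knots,threshold_knots feature knots per variable.
#' @param r_threshold,min_contribution variable-screening thresholds.
#' @param class_breaks suitability class thresholds.
#' @param n_replicates,test_fraction replicate evaluation settings.
#' @param max_iterations,tol fitting controls.
#' @param prevalence logistic prevalence.
#' @param split_year trend demarcation year.
#' @param min_presences refuse modeling below this many thinned presences.
#' @param seed master seed; stage seeds are fixed offsets from it.
#' @return a `runConfig` list.
#' @export
runConfig <- function(species, current, scenarios = list(),
                      background_size = 10000,
                      fcs = FC_ORDER, rms = seq(0.5, 4, by = 0.5),
                      hinge_knots = 50, threshold_knots = 20,
                      r_threshold = 0.8, min_contribution = 1.0,
                      class_breaks = c(0.2, 0.4, 0.6),
                      n_replicates = 10, test_fraction = 0.25,
                      max_iterations = 1000, tol = 1e-5,
                      prevalence = 0.5, split_year = 2000,
                      min_presences = 10, seed = 1) {
  structure(list(
    species = species, current = current, scenarios = scenarios,
    background_size = background_size, fcs = fcs, rms = rms,
    hinge_knots = hinge_knots, threshold_knots = threshold_knots,
    r_threshold = r_threshold, min_contribution = min_contribution,
    class_breaks = class_breaks, n_replicates = n_replicates,
    test_fraction = test_fraction, max_iterations = max_iterations,
    tol = tol, prevalence = prevalence, split_year = split_year,
    min_presences = min_presences, seed = seed
  ), class = "runConfig")
}

#' Read a run configuration from a YAML file
#'
#' Relative paths are resolved against the file's directory. The YAML
#' mirrors [runConfig()]'s arguments; stacks are given as
#' `layers: {name: path.asc, ...}` maps.
#'
#' @param path YAML file.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  species <- lapply(y$species, function(s) {
    list(name = s$name, occurrences = resolve(s$occurrences))
  })
  stack_entry <- function(e) {
    p <- unlist(e$layers)
    stats::setNames(resolve(p), names(p))
  }
  current <- stack_entry(y$current)
  scenarios <- lapply(y$scenarios, function(e) {
    list(label = e$label, group = e$group, stack = stack_entry(e))
  })
  args <- y[setdiff(names(y), c("species", "current", "scenarios"))]
  do.call(runConfig, c(list(species = species, current = current,
                            scenarios = scenarios), args))
}

resolveStack <- function(x, label = "current") {
  if (is(x, "EnvStack")) return(x)
  buildStack(x, scenario = label)
}

resolveOccurrences <- function(x, name) {
  if (is(x, "OccurrenceSet")) return(x)
  readOccurrences(x, name)
}

#' Validate a run configuration before computing
#'
#' Fails fast: checks that every referenced path exists, that all stacks
#' share one grid, that class thresholds are ascending in (0, 1) and that
#' tuning grids are non-empty. Returns all problems, not just the first.
#'
#' @param config a [runConfig()] list.
#' @return list with `ok` (logical) and `problems` (character vector).
#' @export
validateConfig <- function(config) {
  problems <- character(0)
  for (s in config$species) {
    if (is.character(s$occurrences) && !file.exists(s$occurrences)) {
      problems <- c(problems,
                    sprintf("occurrence file missing: %s", s$occurrences))
    }
  }
  check_paths <- function(x, label) {
    if (!is.character(x)) return(invisible())
    miss <- x[!file.exists(x)]
    if (length(miss)) {
      problems <<- c(problems, sprintf("%s: raster missing: %s", label, miss))
    }
  }
  check_paths(config$current, "current")
  for (sc in config$scenarios) check_paths(sc$stack, sc$label)
  if (length(problems) == 0L) {
    cur <- try(resolveStack(config$current), silent = TRUE)
    if (inherits(cur, "try-error")) {
      problems <- c(problems, paste("current stack:", attr(cur, "condition")$message))
    } else {
      for (sc in config$scenarios) {
        st <- try(resolveStack(sc$stack, sc$label), silent = TRUE)
        if (inherits(st, "try-error")) {
          problems <- c(problems, sprintf("%s: %s", sc$label,
                                          attr(st, "condition")$message))
        } else if (!sameGrid(cur@grid, st@grid)) {
          problems <- c(problems,
                        sprintf("%s: grid differs from current stack", sc$label))
        }
      }
    }
  }
  b <- config$class_breaks
  if (length(b) != 3 || any(diff(b) <= 0) || b[1] <= 0 || b[3] >= 1) {
    problems <- c(problems,
                  "class_breaks must be three ascending values in (0, 1)")
  }
  if (length(config$fcs) < 1 || length(config$rms) < 1) {
    problems <- c(problems, "empty tuning grid")
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Run the full study pipeline
#'
#' Per species: clean and thin occurrences on the environmental grid;
#' pre-model on all variables (LQHPT, rm = 1) for percent contributions;
#' screen variables by contribution and Spearman correlation; tune FC x RM
#' by AICc; replicate train/test fits giving per-replicate AUCs and a mean
#' logistic map; jackknife importance and response curves; classify the
#' map; and, per scenario, project the replicate models, classify,
#' summarize gain/loss/net area and centroid shifts ("distance 1" from the
#' current centroid, "distance 2" from the previous period of the same
#' scenario group); finally the elevation-year trend split at the
#' demarcation year. A failure in one species is caught and reported;
#' other species still run. Fixed config + seed gives bit-identical
#' outputs.
#'
#' @param config a [runConfig()] list.
#' @param out_dir optional directory: tables are written as CSV, maps as
#'   ESRI ASCII grids, the log as JSON.
#' @return a run bundle: per-species results plus `thinning` and `log`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  val <- validateConfig(config)
  if (!val$ok) {
    stop("invalid config:\n", paste("-", val$problems, collapse = "\n"))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  current <- resolveStack(config$current)
  scen_stacks <- lapply(config$scenarios, function(sc) {
    resolveStack(sc$stack, sc$label)
  })
  seed <- as.integer(config$seed)
  log <- list(seed = seed, started = "fixed-config run")
  results <- list()
  thinned_sets <- list()

  for (sp in config$species) {
    name <- sp$name
    res <- try({
      occ <- resolveOccurrences(sp$occurrences, name)
      occ <- cleanOccurrences(occ)
      thin <- thinOccurrences(occ, current@grid, seed = seed + 11L)
      thinned_sets[[name]] <- thin
      if (nrow(thin@records) < config$min_presences) {
        stop(sprintf("only %d thinned presences (< %d): refusing to model",
                     nrow(thin@records), config$min_presences))
      }
      presence <- extractSamples(current, thin)
      n_avail <- sum(rowSums(is.na(stackMatrix(current))) == 0)
      n_bg <- min(config$background_size, n_avail)
      background <- sampleBackground(current, n_bg, seed = seed + 23L)
      sm <- bindSamples(presence, background)

      ## pre-model on all candidate variables for screening
      pre <- fitMaxent(sm, fc = "LQHPT", rm = 1,
                       hinge_knots = config$hinge_knots,
                       threshold_knots = config$threshold_knots,
                       max_iterations = config$max_iterations,
                       tol = config$tol)
      contrib <- percentContribution(pre)
      corr <- spearmanMatrix(sm)
      screen <- selectVariables(contrib, corr,
                                r_threshold = config$r_threshold,
                                min_contribution = config$min_contribution)
      keep <- screen$keep
      if (length(keep) == 0L) keep <- names(which.max(contrib))
      sm_kept <- selectColumns(sm, keep)

      tune <- tuneMaxent(sm_kept, fcs = config$fcs, rms = config$rms,
                         hinge_knots = config$hinge_knots,
                         threshold_knots = config$threshold_knots,
                         max_iterations = config$max_iterations,
                         tol = config$tol)
      reps <- replicateEvaluation(
        sm_kept, fc = tune$fc, rm = tune$rm, stack = current,
        n_replicates = config$n_replicates,
        test_fraction = config$test_fraction, seed = seed + 37L,
        hinge_knots = config$hinge_knots,
        threshold_knots = config$threshold_knots,
        max_iterations = config$max_iterations, tol = config$tol
      )
      jack <- jackknifeImportance(sm_kept, fc = tune$fc, rm = tune$rm,
                                  hinge_knots = config$hinge_knots,
                                  threshold_knots = config$threshold_knots,
                                  max_iterations = config$max_iterations,
                                  tol = config$tol)
      curves <- lapply(stats::setNames(keep, keep), function(v) {
        responseCurve(tune$model, v, prevalence = config$prevalence)
      })
      cls_current <- classifySuitability(reps$mean_map,
                                         breaks = config$class_breaks)
      cen_current <- rangeCentroid(cls_current)

      scen_rows <- list()
      maps <- list(current = reps$mean_map)
      classified <- list(current = cls_current)
      prev_centroid <- list()  # per group
      for (i in seq_along(config$scenarios)) {
        sc <- config$scenarios[[i]]
        mp <- meanProjection(reps$models, scen_stacks[[i]],
                             prevalence = config$prevalence)
        cls <- classifySuitability(mp, breaks = config$class_breaks)
        cm <- changeMap(cls_current, cls)
        cen <- rangeCentroid(cls)
        d1 <- if (cen$n_cells > 0 && cen_current$n_cells > 0) {
          centroidShift(cen_current, cen)
        } else NULL
        prev <- prev_centroid[[sc$group %||% sc$label]]
        d2 <- if (!is.null(prev) && cen$n_cells > 0) {
          centroidShift(prev, cen)
        } else d1
        ar <- classAreas(cls)
        scen_rows[[sc$label]] <- data.frame(
          species = name, scenario = sc$label,
          area_high = round(ar$area[ar$class == "high"], 2),
          area_moderate = round(ar$area[ar$class == "moderate"], 2),
          area_general = round(ar$area[ar$class == "general"], 2),
          gained = round(cm$summary$gained, 2),
          lost = round(cm$summary$lost, 2),
          net = round(cm$summary$gained, 2) - round(cm$summary$lost, 2),
          distance1_km = if (is.null(d1)) NA_real_ else d1$distance_km,
          distance2_km = if (is.null(d2)) NA_real_ else d2$distance_km,
          octant = if (is.null(d1)) "none" else d1$octant
        )
        prev_centroid[[sc$group %||% sc$label]] <- cen
        maps[[sc$label]] <- mp
        classified[[sc$label]] <- cls
      }
      trend <- fitTrend(occ, split_year = config$split_year)

      list(
        species = name, thinning = attr(thin, "report"),
        screening = screen, contributions = contrib,
        kept_variables = keep, tuning = tune$results,
        fc = tune$fc, rm = tune$rm, model = tune$model,
        replicate_auc = reps$auc, mean_auc = reps$mean_auc,
        auc_grade = reps$grade, jackknife = jack, response_curves = curves,
        maps = maps, classified = classified,
        current_areas = classAreas(cls_current),
        change = if (length(scen_rows)) do.call(rbind, scen_rows) else NULL,
        centroid_current = cen_current, trend = trend
      )
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      results[[name]] <- list(species = name, error = as.character(res))
      warning(sprintf("species '%s' failed: %s", name, as.character(res)))
    } else {
      results[[name]] <- res
    }
  }

  bundle <- list(species = results,
                 thinning = if (length(thinned_sets)) {
                   thinningSummary(thinned_sets)
                 } else NULL,
                 seed = seed, config = config)
  if (!is.null(out_dir)) writeBundle(bundle, out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean logistic projection of replicate models
#'
#' @param models list of [MaxentModel-class] fits.
#' @param stack an [EnvStack-class].
#' @param prevalence logistic prevalence.
#' @return a [GridLayer-class]: cellwise mean of the per-model logistic
#'   maps.
#' @export
meanProjection <- function(models, stack, prevalence = 0.5) {
  acc <- NULL
  for (m in models) {
    v <- predictLogistic(m, stack, prevalence = prevalence)@values
    acc <- if (is.null(acc)) v else acc + v
  }
  gridLayer(stack@grid, acc / length(models))
}

writeBundle <- function(bundle, out_dir) {
  for (name in names(bundle$species)) {
    res <- bundle$species[[name]]
    if (!is.null(res$error)) next
    pfx <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", name))
    utils::write.csv(res$tuning, paste0(pfx, "_tuning.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(variable = names(res$contributions),
                 percent_contribution = unname(res$contributions)),
      paste0(pfx, "_contribution.csv"), row.names = FALSE
    )
    utils::write.csv(res$jackknife$table, paste0(pfx, "_jackknife.csv"),
                     row.names = FALSE)
    if (!is.null(res$change)) {
      utils::write.csv(res$change, paste0(pfx, "_change.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(res$trend, paste0(pfx, "_trend.csv"),
                     row.names = FALSE)
    for (lbl in names(res$maps)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", lbl)
      writeAsciiGrid(res$maps[[lbl]], paste0(pfx, "_suit_", safe, ".asc"))
      writeClassified(res$classified[[lbl]],
                      paste0(pfx, "_class_", safe, ".asc"))
    }
  }
  if (!is.null(bundle$thinning)) {
    utils::write.csv(bundle$thinning, file.path(out_dir, "thinning.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = bundle$seed,
         species = names(bundle$species),
         failed = names(Filter(function(x) !is.null(x$error),
                               bundle$species))),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE
  )
  invisible(out_dir)
}
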