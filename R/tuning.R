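#' Small-sample AIC for a fitted model
#'
#' Raw scores are standardized to sum to 1 over the model landscape; the
#' log-likelihood is the summed log standardized score at the presence
#' rows; `k` is the number of nonzero feature weights; and
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n - k - 1)` with `n` presences. The
#' candidate is flagged invalid (excluded from ranking) when
#' `k >= n - 1`.
#'
#' @param model a [MaxentModel-class].
#' @param sm the [SampleMatrix-class] the model was fitted on (presence
#'   rows supply the likelihood; all rows rebuild the landscape).
#' @return list with `lnL`, `k`, `aicc`, `valid`.
#' @export
computeAICc <- function(model, sm) {
  pres <- sm@label == "presence"
  key <- ifelse(is.na(sm@cell),
                paste0("xy:", apply(sm@data, 1, paste, collapse = ",")),
                paste0("c:", sm@cell))
  land <- which(!duplicated(key))
  eta_land <- modelEta(model, sm@data[land, , drop = FALSE])
  M <- max(eta_land)
  logZ <- M + log(sum(exp(eta_land - M)))
  eta_pres <- modelEta(model, sm@data[pres, , drop = FALSE])
  lnL <- sum(eta_pres - logZ)
  k <- nParams(model)
  n <- sum(pres)
  if (k >= n - 1) {
    return(list(lnL = lnL, k = k, aicc = NA_real_, valid = FALSE))
  }
  aicc <- 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  list(lnL = lnL, k = k, aicc = aicc, valid = TRUE)
}

#' ROC AUC by the rank-sum statistic
#'
#' `P(score_presence > score_background) + 0.5 P(tie)`, computed from
#' pooled ranks (equivalent to the Mann-Whitney statistic). The accuracy
#' grade follows the conventional bands: excellent `[0.9, 1]`, good
#' `[0.8, 0.9)`, average `[0.7, 0.8)`, poor below 0.7.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return list with `auc` and `grade`.
#' @export
aucScore <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m >= 1, n >= 1)
  r <- rank(c(presence_scores, background_scores))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  grade <- if (auc >= 0.9) "excellent"
           else if (auc >= 0.8) "good"
           else if (auc >= 0.7) "average"
           else "poor"
  list(auc = auc, grade = grade)
}

#' Tune feature class and regularization multiplier by AICc
#'
#' Fits one model per (FC, RM) combination — 6 feature classes by 8
#' multipliers = 48 candidates by default — and selects the minimum-AICc
#' candidate (`delta_aicc = 0`). Exact ties are broken toward the higher
#' RM, then the simpler feature class (order `L < LQ < H < LQH < LQHP <
#' LQHPT`), biasing selection toward parsimony.
#'
#' @param sm a [SampleMatrix-class].
#' @param fcs feature classes to try.
#' @param rms regularization multipliers to try.
#' @param hinge_knots,threshold_knots,max_iterations,tol passed to
#'   [fitMaxent()].
#' @param verbose print one line per candidate.
#' @return list with `results` (data.frame: `fc`, `rm`, `lnL`, `k`,
#'   `aicc`, `delta_aicc`, `auc_train`, `valid`, `selected`), `fc`, `rm`
#'   and `model` (the refitted selected candidate).
#' @export
tuneMaxent <- function(sm, fcs = FC_ORDER,
                       rms = seq(0.5, 4, by = 0.5),
                       hinge_knots = 50, threshold_knots = 20,
                       max_iterations = 1000, tol = 1e-5,
                       verbose = FALSE) {
  stopifnot(length(fcs) >= 1, length(rms) >= 1)
  grid <- expand.grid(fc = fcs, rm = rms, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  ## evaluate in a reproducible, readable order: fc-major, rm ascending
  grid <- grid[order(match(grid$fc, fcs), grid$rm), , drop = FALSE]
  pres <- sm@label == "presence"
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- fitMaxent(sm, fc = grid$fc[i], rm = grid$rm[i],
                     hinge_knots = hinge_knots,
                     threshold_knots = threshold_knots,
                     max_iterations = max_iterations, tol = tol)
    ic <- computeAICc(fit, sm)
    sc <- modelEta(fit, sm@data)
    a <- aucScore(sc[pres], sc[!pres])
    rows[[i]] <- data.frame(
      fc = grid$fc[i], rm = grid$rm[i], lnL = ic$lnL, k = ic$k,
      aicc = ic$aicc, auc_train = a$auc, valid = ic$valid
    )
    models[[i]] <- fit
    if (verbose) {
      message(sprintf("fc=%-6s rm=%.1f  k=%3d  lnL=%.2f  AICc=%s",
                      grid$fc[i], grid$rm[i], ic$k, ic$lnL,
                      if (ic$valid) sprintf("%.2f", ic$aicc) else "invalid"))
    }
  }
  res <- do.call(rbind, rows)
  if (!any(res$valid)) stop("no valid candidate (k >= n - 1 everywhere)")
  best_aicc <- min(res$aicc[res$valid])
  res$delta_aicc <- res$aicc - best_aicc
  tied <- which(res$valid & res$delta_aicc == 0)
  if (length(tied) > 1L) {
    ord <- order(-res$rm[tied], match(res$fc[tied], FC_ORDER))
    tied <- tied[ord]
  }
  sel <- tied[1]
  res$selected <- seq_len(nrow(res)) == sel
  rownames(res) <- NULL
  list(results = res, fc = res$fc[sel], rm = res$rm[sel],
       model = models[[sel]])
}

#' Replicate train/test evaluation and mean suitability map
#'
#' Repeats: hold out a random fraction of the presences, refit on the
#' remaining presences plus the full background, score the held-out
#' presences against the background by AUC, and (optionally) project the
#' replicate model. The final map is the cellwise arithmetic mean of the
#' replicate logistic maps.
#'
#' @param sm a [SampleMatrix-class].
#' @param fc,rm selected feature class and regularization multiplier.
#' @param stack optional [EnvStack-class] to project each replicate onto.
#' @param n_replicates number of replicates (default 10).
#' @param test_fraction held-out presence fraction (default 0.25).
#' @param seed integer seed; replicate `i` uses `seed + i`.
#' @param hinge_knots,threshold_knots,max_iterations,tol passed to
#'   [fitMaxent()].
#' @return list with `auc` (per replicate), `mean_auc`, `grade` (of the
#'   mean AUC), `mean_map` ([GridLayer-class] or `NULL`), `models` and
#'   `splits`.
#' @export
replicateEvaluation <- function(sm, fc, rm, stack = NULL,
                                n_replicates = 10, test_fraction = 0.25,
                                seed = 1, hinge_knots = 50,
                                threshold_knots = 20,
                                max_iterations = 1000, tol = 1e-5) {
  pres_idx <- which(sm@label == "presence")
  bg_idx <- which(sm@label == "background")
  n_test <- max(1L, round(length(pres_idx) * test_fraction))
  if (n_test >= length(pres_idx)) stop("test fraction leaves no training presences")
  aucs <- numeric(n_replicates)
  maps <- NULL
  models <- vector("list", n_replicates)
  splits <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(as.integer(seed) + i)
    test <- sort(sample(pres_idx, n_test))
    train <- setdiff(pres_idx, test)
    fit <- fitMaxent(subsetRows(sm, c(train, bg_idx)), fc = fc, rm = rm,
                     hinge_knots = hinge_knots,
                     threshold_knots = threshold_knots,
                     max_iterations = max_iterations, tol = tol)
    sc_test <- modelEta(fit, sm@data[test, , drop = FALSE])
    sc_bg <- modelEta(fit, sm@data[bg_idx, , drop = FALSE])
    aucs[i] <- aucScore(sc_test, sc_bg)$auc
    if (!is.null(stack)) {
      mp <- predictLogistic(fit, stack)@values
      maps <- if (is.null(maps)) mp else maps + mp
    }
    models[[i]] <- fit
    splits[[i]] <- test
  }
  mean_map <- if (!is.null(maps)) {
    gridLayer(stack@grid, maps / n_replicates)
  } else NULL
  mean_auc <- mean(aucs)
  grade <- if (mean_auc >= 0.9) "excellent"
           else if (mean_auc >= 0.8) "good"
           else if (mean_auc >= 0.7) "average"
           else "poor"
  list(auc = aucs, mean_auc = mean_auc, grade = grade,
       mean_map = mean_map, models = models, splits = splits)
}
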