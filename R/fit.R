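#' Fit a maximum-entropy presence-background model
#'
#' Maximizes the L1-regularized gain
#' \deqn{G(\lambda) = \frac{1}{m}\sum_{presences} \sum_j \lambda_j f_j(x_i)
#'   - \ln Z(\lambda) + \ln N - \sum_j \beta_j^{eff} |\lambda_j|}
#' over the deduplicated presence-union-background landscape of `N` cells
#' (`+ ln N` anchors the gain of the uniform model at 0), by cyclic
#' coordinate descent with an exact soft-threshold step and backtracking,
#' so the gain never decreases on an accepted update. The gain increment of
#' every accepted update is credited to the updated feature's variable
#' (split equally for products), which is the basis of percent
#' contribution. Effective penalties are
#' `rm * defaultBeta(kind, m) * sd(feature | background) / sqrt(m)`.
#'
#' @param sm a [SampleMatrix-class] with >= 2 presence and >= 2 background
#'   rows.
#' @param fc feature-class label (see [featureKinds()]).
#' @param rm regularization multiplier (> 0).
#' @param hinge_knots,threshold_knots knots per variable (see
#'   [expandFeatures()]).
#' @param max_iterations maximum coordinate-descent sweeps.
#' @param tol stop when a full sweep improves the gain by less than this
#'   and no inactive feature violates its optimality condition.
#' @return a [MaxentModel-class].
#' @export
fitMaxent <- function(sm, fc = "LQH", rm = 1,
                      hinge_knots = 50, threshold_knots = 20,
                      max_iterations = 1000, tol = 1e-5) {
  pres <- sm@label == "presence"
  bg <- !pres
  if (sum(pres) < 2 || sum(bg) < 2) {
    stop("need at least 2 presence and 2 background rows")
  }
  ex <- expandFeatures(sm, fc, hinge_knots, threshold_knots)
  feats <- ex$features
  bounds <- ex$bounds

  ## landscape = deduplicated presence-union-background cells
  key <- ifelse(is.na(sm@cell),
                paste0("xy:", apply(sm@data, 1, paste, collapse = ",")),
                paste0("c:", sm@cell))
  land_rows <- which(!duplicated(key))
  F_all <- featureMatrix(feats, bounds, sm@data)
  Fl <- F_all[land_rows, , drop = FALSE]
  m <- sum(pres)
  N <- length(land_rows)
  mu <- unname(colMeans(F_all[pres, , drop = FALSE]))

  rng <- apply(Fl, 2, function(x) diff(range(x)))
  if (all(rng == 0)) stop("degenerate sample matrix: all features constant")

  base <- unname(vapply(feats$kind, defaultBeta, numeric(1), n_presence = m))
  sd_bg <- apply(F_all[bg, , drop = FALSE], 2, stats::sd)
  beta_eff <- rm * base * pmax(sd_bg, 1e-4) / sqrt(m)

  K <- ncol(Fl)
  lambda <- numeric(K)
  eta <- numeric(N)
  logN <- log(N)
  lse <- function(e) { M <- max(e); M + log(sum(exp(e - M))) }
  cur_lse <- logN
  p <- rep(1 / N, N)
  lin <- 0; pen <- 0
  gain <- 0
  var_names <- colnames(sm@data)
  varGain <- stats::setNames(numeric(length(var_names)), var_names)

  soft <- function(x, t) sign(x) * max(abs(x) - t, 0)
  it <- 0L
  converged <- FALSE
  while (it < max_iterations) {
    it <- it + 1L
    grad_all <- mu - as.vector(crossprod(Fl, p))
    active <- which(lambda != 0 | abs(grad_all) > beta_eff + 1e-12)
    sweep0 <- gain
    for (j in active) {
      fj <- Fl[, j]
      Ef <- sum(p * fj)
      curv <- max(sum(p * fj * fj) - Ef * Ef, 1e-10)
      g <- mu[j] - Ef
      lam_new <- soft(lambda[j] * curv + g, beta_eff[j]) / curv
      delta <- lam_new - lambda[j]
      if (abs(delta) < 1e-12) next
      ## cap the step so gain accrues gradually: per-variable credit then
      ## reflects the optimization path rather than sweep order
      if (abs(delta) > 0.25) delta <- sign(delta) * 0.25
      accepted <- FALSE
      for (bt in 1:40) {
        lam_try <- lambda[j] + delta
        eta_try <- eta + delta * fj
        lse_try <- lse(eta_try)
        lin_try <- lin + mu[j] * delta
        pen_try <- pen + beta_eff[j] * (abs(lam_try) - abs(lambda[j]))
        gain_try <- lin_try - (lse_try - logN) - pen_try
        if (gain_try >= gain - 1e-12) { accepted <- TRUE; break }
        delta <- delta / 2
        if (abs(delta) < 1e-13) break
      }
      if (!accepted) next
      inc <- gain_try - gain
      lambda[j] <- lam_try
      eta <- eta_try
      cur_lse <- lse_try
      p <- exp(eta - cur_lse)
      lin <- lin_try; pen <- pen_try; gain <- gain_try
      if (feats$kind[j] == "product") {
        varGain[feats$var1[j]] <- varGain[feats$var1[j]] + inc / 2
        varGain[feats$var2[j]] <- varGain[feats$var2[j]] + inc / 2
      } else {
        varGain[feats$var1[j]] <- varGain[feats$var1[j]] + inc
      }
    }
    if (gain - sweep0 < tol) {
      grad_all <- mu - as.vector(crossprod(Fl, p))
      if (!any(lambda == 0 & abs(grad_all) > beta_eff + 1e-3)) {
        converged <- TRUE
        break
      }
    }
  }

  entropy <- { q <- p[p > 0]; -sum(q * log(q)) }
  new("MaxentModel",
    features = feats, bounds = bounds, lambdas = lambda, beta = beta_eff,
    fc = fc, rm = rm, logZ = cur_lse, entropy = entropy, gain = gain,
    varGain = varGain,
    presenceMeans = colMeans(sm@data[pres, , drop = FALSE]),
    nPresence = as.integer(m), nLandscape = as.integer(N),
    iterations = it, converged = converged
  )
}

setMethod("show", "MaxentModel", function(object) {
  cat(sprintf(
    paste0("MaxentModel fc=%s rm=%g: %d/%d nonzero features, gain %.4f ",
           "nats, H %.4f nats\n  %d presences over %d landscape cells; ",
           "%d sweeps%s\n"),
    object@fc, object@rm, sum(object@lambdas != 0), length(object@lambdas),
    object@gain, object@entropy, object@nPresence, object@nLandscape,
    object@iterations, if (object@converged) "" else " (not converged)"
  ))
})

#' Number of nonzero feature weights
#' @param model a [MaxentModel-class].
#' @return integer count.
#' @export
nParams <- function(model) sum(model@lambdas != 0)

## Raw variable matrix from the supported evaluation inputs. For an
## EnvStack, returns data-cell rows plus the index map back to the grid.
evalMatrix <- function(model, newdata) {
  if (is(newdata, "SampleMatrix")) {
    list(X = newdata@data, cells = NULL, grid = NULL)
  } else if (is(newdata, "EnvStack")) {
    X <- stackMatrix(newdata)[, colnames(model@bounds), drop = FALSE]
    ok <- which(rowSums(is.na(X)) == 0)
    list(X = X[ok, , drop = FALSE], cells = ok, grid = newdata@grid)
  } else {
    X <- as.matrix(newdata)
    list(X = X[, colnames(model@bounds), drop = FALSE], cells = NULL,
         grid = NULL)
  }
}

modelEta <- function(model, X) {
  as.vector(featureMatrix(model@features, model@bounds, X) %*% model@lambdas)
}

#' Raw (relative occurrence rate) predictions
#'
#' With `normalize = "self"` the returned probabilities sum to 1 over the
#' evaluation set; with `"training"` they are normalized by the model's
#' training-landscape normalizer (the scale the logistic and cloglog
#' transforms are defined on).
#'
#' @param model a [MaxentModel-class].
#' @param newdata a [SampleMatrix-class], [EnvStack-class], or numeric
#'   matrix/data.frame with the model's variables as columns.
#' @param normalize `"self"` or `"training"`.
#' @return numeric vector; for an [EnvStack-class], a [GridLayer-class].
#' @export
predictRaw <- function(model, newdata, normalize = c("self", "training")) {
  normalize <- match.arg(normalize)
  ev <- evalMatrix(model, newdata)
  eta <- modelEta(model, ev$X)
  p <- if (normalize == "self") {
    M <- max(eta)
    w <- exp(eta - M)
    w / sum(w)
  } else {
    exp(eta - model@logZ)
  }
  wrapPrediction(p, ev)
}

wrapPrediction <- function(v, ev) {
  if (is.null(ev$grid)) return(v)
  m <- matrix(NA_real_, ev$grid@nrow, ev$grid@ncol)
  mt <- t(m)
  mt[ev$cells] <- v
  gridLayer(ev$grid, t(mt))
}

#' Logistic transform of a raw prediction
#'
#' `logistic = c * praw / (1 + c * praw)` with
#' `c = prevalence/(1 - prevalence) * exp(H)`, `H` the entropy of the
#' fitted raw distribution and `praw` the training-normalized raw score.
#' At the default prevalence 0.5 a cell typical of the training landscape
#' scores 0.5.
#'
#' @param praw training-normalized raw scores.
#' @param entropy raw-distribution entropy in nats.
#' @param prevalence assumed species prevalence (default 0.5).
#' @return values in (0, 1).
#' @export
logisticOutput <- function(praw, entropy, prevalence = 0.5) {
  v <- prevalence / (1 - prevalence) * exp(entropy) * praw
  v / (1 + v)
}

#' Complementary log-log transform of a raw prediction
#'
#' `cloglog = 1 - exp(-exp(H) * praw)`; pointwise at least as large as the
#' logistic output.
#'
#' @inheritParams logisticOutput
#' @return values in (0, 1).
#' @export
cloglogOutput <- function(praw, entropy) {
  1 - exp(-exp(entropy) * praw)
}

#' Logistic suitability predictions
#' @inheritParams predictRaw
#' @param prevalence assumed prevalence (default 0.5).
#' @return suitability in (0, 1); for an [EnvStack-class] a
#'   [GridLayer-class].
#' @export
predictLogistic <- function(model, newdata, prevalence = 0.5) {
  ev <- evalMatrix(model, newdata)
  praw <- exp(modelEta(model, ev$X) - model@logZ)
  wrapPrediction(logisticOutput(praw, model@entropy, prevalence), ev)
}

#' Cloglog suitability predictions
#' @inheritParams predictRaw
#' @return suitability in (0, 1); for an [EnvStack-class] a
#'   [GridLayer-class].
#' @export
predictCloglog <- function(model, newdata) {
  ev <- evalMatrix(model, newdata)
  praw <- exp(modelEta(model, ev$X) - model@logZ)
  wrapPrediction(cloglogOutput(praw, model@entropy), ev)
}

#' Project a fitted model onto an environmental stack
#'
#' @param model a [MaxentModel-class].
#' @param stack an [EnvStack-class] carrying the model's variables.
#' @param type `"logistic"` (default), `"cloglog"` or `"raw"` (raw is
#'   normalized to sum to 1 over the stack's data cells).
#' @param prevalence prevalence for the logistic transform.
#' @return a [GridLayer-class].
#' @export
projectModel <- function(model, stack,
                         type = c("logistic", "cloglog", "raw"),
                         prevalence = 0.5) {
  type <- match.arg(type)
  switch(type,
    logistic = predictLogistic(model, stack, prevalence),
    cloglog = predictCloglog(model, stack),
    raw = predictRaw(model, stack, normalize = "self")
  )
}

#' Serialize a fitted model to JSON
#'
#' Stores feature definitions, training bounds, weights, penalties,
#' normalizer and entropy — enough to re-project without refitting.
#'
#' @param model a [MaxentModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelJson <- function(model, path) {
  obj <- list(
    fc = model@fc, rm = model@rm,
    features = model@features, bounds = as.data.frame(model@bounds),
    lambdas = model@lambdas, beta = model@beta,
    logZ = model@logZ, entropy = model@entropy, gain = model@gain,
    varGain = as.list(model@varGain),
    presenceMeans = as.list(model@presenceMeans),
    nPresence = model@nPresence, nLandscape = model@nLandscape
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized by [writeModelJson()]
#' @param path JSON file.
#' @return a [MaxentModel-class].
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- as.matrix(obj$bounds)
  rownames(bounds) <- c("min", "max")
  new("MaxentModel",
    features = as.data.frame(obj$features), bounds = bounds,
    lambdas = as.numeric(obj$lambdas), beta = as.numeric(obj$beta),
    fc = obj$fc, rm = obj$rm, logZ = obj$logZ, entropy = obj$entropy,
    gain = obj$gain, varGain = unlist(obj$varGain),
    presenceMeans = unlist(obj$presenceMeans),
    nPresence = as.integer(obj$nPresence),
    nLandscape = as.integer(obj$nLandscape),
    iterations = 0L, converged = TRUE
  )
}
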