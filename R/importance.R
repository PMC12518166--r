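#' Pairwise Spearman rank correlations
#'
#' Computed by default on presence rows only (variable screening concerns
#' the species' occupied environment); set `rows = "all"` to use presence
#' and background together. Ties take average ranks.
#'
#' @param sm a [SampleMatrix-class] with >= 3 usable rows.
#' @param rows `"presence"` or `"all"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(sm, rows = c("presence", "all")) {
  rows <- match.arg(rows)
  X <- if (rows == "presence") {
    sm@data[sm@label == "presence", , drop = FALSE]
  } else sm@data
  if (nrow(X) < 3) stop("need at least 3 rows for rank correlation")
  stats::cor(X, method = "spearman")
}

#' Screen variables by contribution and collinearity
#'
#' Greedy rule: sort variables by descending percent contribution; accept
#' a variable iff its absolute Spearman correlation with every
#' already-accepted variable is below `r_threshold`; finally drop accepted
#' variables contributing less than `min_contribution` percent. Every
#' exclusion is recorded with its cause (and correlated partner).
#'
#' @param contrib named numeric percent contributions (summing to ~100).
#' @param corr correlation matrix covering the same variables.
#' @param r_threshold exclusion threshold on `|r|` (default 0.8: a pair
#'   with `|r| >= 0.8` keeps only the higher contributor).
#' @param min_contribution minimum percent contribution kept (default 1).
#' @return list with `keep` (character vector) and `audit` (data.frame:
#'   `variable`, `contribution`, `decision`, `reason`, `partner`).
#' @export
selectVariables <- function(contrib, corr, r_threshold = 0.8,
                            min_contribution = 1.0) {
  vars <- names(contrib)
  stopifnot(!is.null(vars), all(vars %in% rownames(corr)))
  ord <- order(-contrib)
  accepted <- character(0)
  audit <- data.frame(variable = character(0), contribution = numeric(0),
                      decision = character(0), reason = character(0),
                      partner = character(0))
  note <- function(v, dec, why, partner = "") {
    audit <<- rbind(audit, data.frame(
      variable = v, contribution = unname(contrib[v]), decision = dec,
      reason = why, partner = partner
    ))
  }
  for (v in vars[ord]) {
    r_with <- if (length(accepted)) abs(corr[v, accepted]) else numeric(0)
    if (any(r_with >= r_threshold)) {
      partner <- accepted[which.max(r_with)]
      note(v, "excluded",
           sprintf("|r| = %.3f >= %.2f with higher contributor",
                   max(r_with), r_threshold), partner)
    } else {
      accepted <- c(accepted, v)
      note(v, "accepted", "passed correlation screen")
    }
  }
  low <- accepted[contrib[accepted] < min_contribution]
  for (v in low) {
    audit$decision[audit$variable == v] <- "excluded"
    audit$reason[audit$variable == v] <-
      sprintf("contribution %.2f%% < %.2f%%", contrib[v], min_contribution)
  }
  keep <- setdiff(accepted, low)
  list(keep = keep[order(match(keep, vars))], audit = audit)
}

#' Percent contribution per variable
#'
#' Normalizes the per-variable gain credits accrued along the optimization
#' path (each accepted coordinate update's gain increment, split equally
#' between the two variables of a product feature) to percentages.
#'
#' @param model a [MaxentModel-class].
#' @return named numeric percentages summing to 100; if no gain was
#'   accrued, all-`NA` with attribute `no_gain = TRUE`.
#' @export
percentContribution <- function(model) {
  g <- pmax(model@varGain, 0)
  tot <- sum(g)
  if (tot <= 0) {
    out <- stats::setNames(rep(NA_real_, length(g)), names(g))
    attr(out, "no_gain") <- TRUE
    return(out)
  }
  100 * g / tot
}

#' Jackknife variable importance
#'
#' For each variable, fits a model using only that variable and a model
#' using all variables except it, recording the regularized training gain
#' of each alongside the full-model gain. With a single variable the
#' without-model cannot be fitted and is reported as `NA`.
#'
#' @param sm a [SampleMatrix-class].
#' @param fc,rm feature class and regularization multiplier.
#' @param ... passed to [fitMaxent()] (knots, iterations, tolerance).
#' @return list with `table` (data.frame: `variable`, `gain_with_only`,
#'   `gain_without`) and `full_gain`.
#' @export
jackknifeImportance <- function(sm, fc, rm, ...) {
  vars <- colnames(sm@data)
  full <- fitMaxent(sm, fc = fc, rm = rm, ...)
  with_only <- numeric(length(vars))
  without <- rep(NA_real_, length(vars))
  for (i in seq_along(vars)) {
    with_only[i] <- fitMaxent(selectColumns(sm, vars[i]),
                              fc = fc, rm = rm, ...)@gain
    if (length(vars) > 1) {
      without[i] <- fitMaxent(selectColumns(sm, vars[-i]),
                              fc = fc, rm = rm, ...)@gain
    }
  }
  list(table = data.frame(variable = vars, gain_with_only = with_only,
                          gain_without = without),
       full_gain = full@gain)
}

#' Marginal response curve of one variable
#'
#' Varies the variable over its training range at `n_points` while holding
#' every other variable at its presence mean, and returns the logistic
#' suitability along that sweep, its argmax (the apparent optimum) and the
#' interval where suitability exceeds 0.5 (conditions conventionally
#' called suitable). The interval is `NA` when the curve never reaches
#' 0.5.
#'
#' @param model a [MaxentModel-class].
#' @param variable variable name.
#' @param n_points abscissa resolution (default 100).
#' @param prevalence logistic prevalence.
#' @return data.frame-based list: `curve` (data.frame `value`,
#'   `suitability`), `optimum`, `suitable_interval` (length-2 numeric or
#'   `NA`).
#' @export
responseCurve <- function(model, variable, n_points = 100,
                          prevalence = 0.5) {
  vars <- colnames(model@bounds)
  if (!variable %in% vars) stop("model has no variable '", variable, "'")
  xs <- seq(model@bounds["min", variable], model@bounds["max", variable],
            length.out = n_points)
  X <- matrix(rep(model@presenceMeans[vars], each = n_points),
              n_points, length(vars), dimnames = list(NULL, vars))
  X[, variable] <- xs
  y <- predictLogistic(model, X, prevalence = prevalence)
  above <- which(y > 0.5)
  interval <- if (length(above)) range(xs[above]) else c(NA_real_, NA_real_)
  list(curve = data.frame(value = xs, suitability = y),
       variable = variable, optimum = xs[which.max(y)],
       suitable_interval = interval)
}

#' Single-variable response curve by refit
#'
#' The alternative response mode: refits a model on the one variable alone
#' and traces its curve, so the response is not confounded by correlated
#' covariates held at presence means.
#'
#' @param sm a [SampleMatrix-class].
#' @param variable variable name.
#' @param fc,rm feature class and regularization multiplier.
#' @param n_points abscissa resolution.
#' @param ... passed to [fitMaxent()].
#' @return as [responseCurve()].
#' @export
singleVariableResponse <- function(sm, variable, fc, rm, n_points = 100,
                                   ...) {
  fit <- fitMaxent(selectColumns(sm, variable), fc = fc, rm = rm, ...)
  responseCurve(fit, variable, n_points = n_points)
}
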