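#' Feature classes
#'
#' The model's flexibility is set by which feature transformations of the
#' environmental variables are admitted: linear (L), quadratic (Q),
#' product (P), hinge (H) and threshold (T). The six canonical sets are
#' `L`, `LQ`, `H`, `LQH`, `LQHP`, `LQHPT`.
#'
#' @param fc feature-class label.
#' @return character vector of feature kinds.
#' @export
featureKinds <- function(fc) {
  kinds <- switch(fc,
    L = "linear",
    LQ = c("linear", "quadratic"),
    H = "hinge",
    LQH = c("linear", "quadratic", "hinge"),
    LQHP = c("linear", "quadratic", "hinge", "product"),
    LQHPT = c("linear", "quadratic", "hinge", "product", "threshold"),
    stop("unknown feature class '", fc, "'; use L, LQ, H, LQH, LQHP or LQHPT")
  )
  kinds
}

#' Canonical feature-class order, simplest first
#' @export
FC_ORDER <- c("L", "LQ", "H", "LQH", "LQHP", "LQHPT")

#' Expand training variables into model features
#'
#' With `d` variables: L gives `d` features, Q another `d`, P all
#' `d(d-1)/2` pairwise products, H `2 * hinge_knots` per variable (a
#' forward and a reverse hinge at each knot) and T `threshold_knots` per
#' variable. Knots are placed at training-data quantiles and stored in raw
#' variable units. All features are evaluated on variables min/max-scaled
#' to `[0, 1]` using the training bounds and clamped outside, so every
#' feature maps into `[0, 1]`. A variable constant over the training data
#' yields constant-zero features and is reported via the `"degenerate"`
#' attribute.
#'
#' @param sm a [SampleMatrix-class] (bounds/knots use all rows).
#' @param fc feature-class label.
#' @param hinge_knots,threshold_knots knots per variable.
#' @return list with `features` (data.frame: `kind`, `var1`, `var2`,
#'   `knot`, `direction`) and `bounds` (2 x d matrix, rows `min`, `max`).
#' @export
expandFeatures <- function(sm, fc, hinge_knots = 50, threshold_knots = 20) {
  X <- sm@data
  vars <- colnames(X)
  bounds <- rbind(min = apply(X, 2, min), max = apply(X, 2, max))
  degenerate <- vars[bounds["max", ] == bounds["min", ]]
  kinds <- featureKinds(fc)

  feats <- list()
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_,
                  direction = NA_character_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, var1 = var1, var2 = var2, knot = knot,
      direction = direction, stringsAsFactors = FALSE
    )
  }
  if ("linear" %in% kinds) for (v in vars) add("linear", v)
  if ("quadratic" %in% kinds) for (v in vars) add("quadratic", v)
  if ("product" %in% kinds && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) {
      for (j in seq(i + 1, length(vars))) add("product", vars[i], vars[j])
    }
  }
  if ("hinge" %in% kinds && hinge_knots > 0) {
    probs <- seq_len(hinge_knots) / (hinge_knots + 1)
    for (v in vars) {
      ks <- as.numeric(stats::quantile(X[, v], probs, names = FALSE))
      for (k in ks) {
        add("hinge", v, knot = k, direction = "forward")
        add("hinge", v, knot = k, direction = "reverse")
      }
    }
  }
  if ("threshold" %in% kinds && threshold_knots > 0) {
    probs <- seq_len(threshold_knots) / (threshold_knots + 1)
    for (v in vars) {
      ks <- as.numeric(stats::quantile(X[, v], probs, names = FALSE))
      for (k in ks) add("threshold", v, knot = k)
    }
  }
  features <- do.call(rbind, feats)
  if (length(degenerate)) {
    message("constant training variable(s), features fixed at 0: ",
            paste(degenerate, collapse = ", "))
  }
  structure(list(features = features, bounds = bounds),
            degenerate = degenerate)
}

## Scale raw variable values into [0,1] by training bounds, clamped.
scale01 <- function(x, lo, hi) {
  if (hi <= lo) return(rep(0, length(x)))
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Evaluate features on raw variable values
#'
#' @param features feature definition data.frame (see [expandFeatures()]).
#' @param bounds training bounds matrix.
#' @param X numeric matrix of raw variable values with named columns.
#' @return numeric matrix, one column per feature, values in `[0, 1]`.
#' @export
featureMatrix <- function(features, bounds, X) {
  Z <- vapply(colnames(bounds), function(v) {
    scale01(X[, v], bounds["min", v], bounds["max", v])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) Z <- matrix(Z, 1, dimnames = list(NULL, colnames(bounds)))
  out <- matrix(0, nrow(X), nrow(features))
  for (j in seq_len(nrow(features))) {
    f <- features[j, ]
    z <- Z[, f$var1]
    out[, j] <- switch(f$kind,
      linear = z,
      quadratic = z^2,
      product = z * Z[, f$var2],
      hinge = {
        zk <- scale01(f$knot, bounds["min", f$var1], bounds["max", f$var1])
        if (f$direction == "forward") {
          if (zk >= 1) 0 * z else pmax(0, z - zk) / (1 - zk)
        } else {
          if (zk <= 0) 0 * z else pmax(0, zk - z) / zk
        }
      },
      threshold = {
        zk <- scale01(f$knot, bounds["min", f$var1], bounds["max", f$var1])
        as.numeric(z >= zk)
      },
      stop("unknown feature kind: ", f$kind)
    )
  }
  out
}

#' Base regularization by feature kind and presence count
#'
#' The per-feature L1 penalty base follows the standard Maxent schedule:
#' piecewise-linear in the number of presences between anchor points,
#' constant beyond the end anchors. Linear/quadratic/product features use
#' anchors (0, 1.0), (10, 1.0), (30, 0.2), (100, 0.05); hinge features a
#' constant 0.5; threshold features (0, 2.0), (100, 1.0). The effective
#' penalty applied during fitting is
#' `rm * beta * sd(feature over background) / sqrt(n_presence)`.
#'
#' @param kind feature kind (`"linear"`, `"quadratic"`, `"product"`,
#'   `"hinge"`, `"threshold"`).
#' @param n_presence number of presence records (>= 1).
#' @return base beta (> 0).
#' @export
defaultBeta <- function(kind, n_presence) {
  stopifnot(n_presence >= 1)
  interp <- function(n, ns, bs) {
    stats::approx(ns, bs, xout = pmin(pmax(n, min(ns)), max(ns)),
                  method = "linear")$y
  }
  switch(kind,
    linear = , quadratic = , product =
      interp(n_presence, c(0, 10, 30, 100), c(1.0, 1.0, 0.2, 0.05)),
    hinge = 0.5,
    threshold = interp(n_presence, c(0, 100), c(2.0, 1.0)),
    stop("unknown feature kind: ", kind)
  )
}
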