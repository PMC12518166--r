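#' Elevation-versus-year trend, split at a demarcation year
#'
#' Ordinary least squares of record elevation on collection year, fitted
#' separately before and after the split year (records at exactly the
#' split year go to the post period by default). Reports the slope
#' (m/year), intercept, R-squared, the two-sided p-value of the slope
#' t-test and a direction call: `up` iff slope > 0 and p < 0.05, `down`
#' iff slope < 0 and p < 0.05, else `none`. Records missing year or
#' elevation are excluded (counts logged in the result); a period with
#' fewer than 3 usable records, or with all-identical years, is reported
#' with status `"insufficient data"` / `"undefined slope"` instead of a
#' fit.
#'
#' @param set an [OccurrenceSet-class] carrying `year` and `elevation`.
#' @param split_year demarcation year (default 2000).
#' @param split_to period receiving records at exactly `split_year`:
#'   `"post"` (default) or `"pre"`.
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per period: `species`, `period`, `n`,
#'   `n_excluded`, `slope`, `intercept`, `r_squared`, `p_value`,
#'   `direction`, `status`.
#' @export
fitTrend <- function(set, split_year = 2000, split_to = c("post", "pre"),
                     alpha = 0.05) {
  split_to <- match.arg(split_to)
  r <- set@records
  usable <- !is.na(r$year) & !is.na(r$elevation)
  n_excluded <- sum(!usable)
  r <- r[usable, , drop = FALSE]
  in_pre <- if (split_to == "post") r$year < split_year else r$year <= split_year
  fit_one <- function(d, period) {
    base <- data.frame(
      species = set@species, period = period, n = nrow(d),
      n_excluded = n_excluded, slope = NA_real_, intercept = NA_real_,
      r_squared = NA_real_, p_value = NA_real_, direction = "none",
      status = "ok"
    )
    if (nrow(d) < 3) {
      base$status <- "insufficient data"
      return(base)
    }
    if (length(unique(d$year)) < 2) {
      base$status <- "undefined slope"
      return(base)
    }
    if (stats::sd(d$elevation) == 0) {
      ## flat response: no variance to explain
      base$slope <- 0; base$intercept <- d$elevation[1]
      base$r_squared <- 0; base$p_value <- 1
      return(base)
    }
    fit <- stats::lm(elevation ~ year, data = d)
    s <- suppressWarnings(summary(fit))  # tolerate numerically perfect fits
    slope <- unname(stats::coef(fit)["year"])
    p <- s$coefficients["year", "Pr(>|t|)"]
    base$slope <- slope
    base$intercept <- unname(stats::coef(fit)["(Intercept)"])
    base$r_squared <- s$r.squared
    base$p_value <- p
    base$direction <- if (is.finite(p) && p < alpha) {
      if (slope > 0) "up" else if (slope < 0) "down" else "none"
    } else "none"
    base
  }
  rbind(
    fit_one(r[in_pre, , drop = FALSE], sprintf("pre%d", split_year)),
    fit_one(r[!in_pre, , drop = FALSE], sprintf("post%d", split_year))
  )
}
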