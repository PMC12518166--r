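test_that("extreme regularization shrinks to the uniform model", {
  set.seed(3)
  nm <- c("a", "b")
  sm <- rawSample(matrix(rnorm(40, 2), 20, 2, dimnames = list(NULL, nm)),
                  matrix(rnorm(80), 40, 2, dimnames = list(NULL, nm)))
  fit <- fitMaxent(sm, fc = "LQ", rm = 1e6)
  expect_true(all(fit@lambdas == 0))
  expect_equal(fit@gain, 0)
  praw <- predictRaw(fit, sm)
  expect_equal(unname(praw), rep(1 / fit@nLandscape, nrow(sm@data)),
               tolerance = 1e-12)
  expect_equal(fit@entropy, log(fit@nLandscape))
})

test_that("one binary feature matches a brute-force 1-D gain search", {
  ## presences all at feature = 1; background half at 1
  pres <- matrix(1, 20, 1, dimnames = list(NULL, "x"))
  bg <- matrix(rep(c(0, 1), 20), 40, 1, dimnames = list(NULL, "x"))
  sm <- rawSample(pres, bg)
  fit <- fitMaxent(sm, fc = "L", rm = 1)
  expect_equal(nrow(fit@features), 1L)

  key <- apply(sm@data, 1, paste, collapse = ",")
  Fl <- sm@data[!duplicated(key), , drop = FALSE]
  mu <- 1
  grid_l <- seq(0, 10, by = 1e-3)
  gains <- vapply(grid_l, function(l) {
    bruteForceGain(Fl, mu, fit@beta, l)
  }, numeric(1))
  expect_equal(fit@lambdas, grid_l[which.max(gains)], tolerance = 1e-3)
  expect_equal(fit@gain, max(gains), tolerance = 1e-6)
})

test_that("coordinate descent attains the exhaustive optimum (<= 3 features)", {
  set.seed(4)
  nm <- c("a", "b")
  pres <- matrix(c(rnorm(15, 1.5, 0.7), rnorm(15, -0.5, 0.7)), 15, 2,
                 dimnames = list(NULL, nm))
  bg <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, nm))
  sm <- rawSample(pres, bg)
  fit <- fitMaxent(sm, fc = "L", rm = 1, tol = 1e-9)

  ex <- expandFeatures(sm, "L")
  key <- apply(sm@data, 1, paste, collapse = ",")
  Fl <- featureMatrix(ex$features, ex$bounds,
                      sm@data[!duplicated(key), , drop = FALSE])
  Fp <- featureMatrix(ex$features, ex$bounds, sm@data[sm@label == "presence", ])
  mu <- colMeans(Fp)
  ## independent optimizer on the same objective
  opt <- optim(c(0, 0), function(l) -bruteForceGain(Fl, mu, fit@beta, l),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit@gain, -opt$value, tolerance = 1e-3)
  expect_gte(fit@gain + 1e-12, -opt$value - 1e-3)
})

test_that("a duplicated feature column leaves the raw distribution unchanged", {
  set.seed(5)
  pres <- matrix(rnorm(20, 1), 20, 1, dimnames = list(NULL, "x"))
  bg <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "x"))
  sm1 <- rawSample(pres, bg)
  sm2 <- rawSample(cbind(pres, x2 = pres[, 1]), cbind(bg, x2 = bg[, 1]))
  f1 <- fitMaxent(sm1, fc = "L", rm = 1, tol = 1e-8)
  f2 <- fitMaxent(sm2, fc = "L", rm = 1, tol = 1e-8)
  p1 <- predictRaw(f1, sm1)
  p2 <- predictRaw(f2, sm2)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("raw predictions are a probability distribution", {
  st <- smallWorld(seed = 6)
  truth <- trueModel(coefficients = c(elev = 1.5))
  sm <- smallSample(st, truth, seed = 6, n_presence = 80, n_background = 400)
  fit <- fitMaxent(sm, fc = "LQ", rm = 1)
  praw <- predictRaw(fit, sm)
  expect_true(all(praw >= 0))
  ## self-normalized over the evaluation set
  expect_equal(sum(praw), 1, tolerance = 1e-8)
  over_stack <- predictRaw(fit, st)
  expect_equal(sum(over_stack@values, na.rm = TRUE), 1, tolerance = 1e-8)
})

test_that("raw score is monotone in a single positive linear feature", {
  pres <- matrix(runif(30, 0.6, 1), 30, 1, dimnames = list(NULL, "x"))
  bg <- matrix(runif(60, 0, 1), 60, 1, dimnames = list(NULL, "x"))
  sm <- rawSample(pres, bg)
  fit <- fitMaxent(sm, fc = "L", rm = 1)
  expect_gt(fit@lambdas[1], 0)
  xs <- matrix(seq(0, 1, 0.1), ncol = 1, dimnames = list(NULL, "x"))
  sc <- predictRaw(fit, xs, normalize = "training")
  expect_true(all(diff(sc) > 0))
})

test_that("logistic and cloglog transforms match their closed forms", {
  ## uniform raw: H = ln N, praw = 1/N
  expect_equal(logisticOutput(1 / 1000, log(1000)), 0.5)
  expect_equal(cloglogOutput(1 / 1000, log(1000)), 1 - exp(-1))
  ## hand-set H = ln 4, praw = 0.5 -> e^H * p = 2 -> logistic 2/3
  expect_equal(logisticOutput(0.5, log(4)), 2 / 3)
  expect_equal(logisticOutput(0, log(4)), 0)
  expect_equal(cloglogOutput(0, log(4)), 0)
  ## cloglog >= logistic pointwise: 1 - e^-z >= z/(1+z) for z >= 0
  z <- 10^seq(-6, 3, length.out = 50)
  H <- log(37)
  expect_true(all(cloglogOutput(z / exp(H) / 1, H) >=
                  logisticOutput(z / exp(H), H) - 1e-12))

  st <- smallWorld(seed = 7)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 1)), seed = 7,
                    n_presence = 60, n_background = 300)
  fit <- fitMaxent(sm, fc = "LQ", rm = 1)
  lg <- predictLogistic(fit, sm)
  cl <- predictCloglog(fit, sm)
  expect_true(all(lg > 0 & lg < 1))
  expect_true(all(cl >= lg - 1e-12))
})

test_that("the nonzero-feature count shrinks as RM grows", {
  st <- smallWorld(seed = 8)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 1.5, bio12 = 0.7)),
                    seed = 8, n_presence = 100, n_background = 500)
  ks <- vapply(c(0.5, 1, 2, 4, 8), function(rm) {
    nParams(fitMaxent(sm, fc = "LQ", rm = rm))
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("affine rescaling of a variable leaves the raw distribution unchanged", {
  set.seed(9)
  nm <- c("a", "b")
  pres <- matrix(rnorm(40, 1), 20, 2, dimnames = list(NULL, nm))
  bg <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, nm))
  sm1 <- rawSample(pres, bg)
  resc <- function(m) { m[, "a"] <- 100 + 42 * m[, "a"]; m }
  sm2 <- rawSample(resc(pres), resc(bg))
  f1 <- fitMaxent(sm1, fc = "LQH", rm = 1, hinge_knots = 8, tol = 1e-8)
  f2 <- fitMaxent(sm2, fc = "LQH", rm = 1, hinge_knots = 8, tol = 1e-8)
  expect_equal(predictRaw(f1, sm1), predictRaw(f2, sm2), tolerance = 1e-6)
})

test_that("degenerate inputs fail explicitly", {
  nm <- "x"
  sm <- rawSample(matrix(3, 10, 1, dimnames = list(NULL, nm)),
                  matrix(3, 10, 1, dimnames = list(NULL, nm)))
  expect_message(expect_error(fitMaxent(sm, fc = "L", rm = 1), "degenerate"))
  one <- rawSample(matrix(1, 1, 1, dimnames = list(NULL, nm)),
                   matrix(0, 1, 1, dimnames = list(NULL, nm)))
  expect_error(fitMaxent(one, fc = "L"), "at least 2")
})

test_that("model JSON serialization re-projects without refitting", {
  st <- smallWorld(seed = 10)
  sm <- smallSample(st, trueModel(coefficients = c(elev = 1)), seed = 10,
                    n_presence = 60, n_background = 300)
  fit <- fitMaxent(sm, fc = "LQH", rm = 1, hinge_knots = 10)
  p <- withr::local_tempfile(fileext = ".json")
  writeModelJson(fit, p)
  back <- readModelJson(p)
  expect_equal(predictLogistic(back, sm), predictLogistic(fit, sm),
               tolerance = 1e-12)
})
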