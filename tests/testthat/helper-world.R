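# Small synthetic worlds shared across test files. Everything is generated
# in code; nothing is read from disk.

smallGrid <- function(nrow = 40, ncol = 40, cellsize = 2.5 / 60) {
  gridSpec(nrow, ncol, xmin = 98, ymin = 28, cellsize = cellsize)
}

# A compact montane world with a cold-quarter temperature layer tied to
# elevation, a precipitation gradient and a pure-noise layer.
smallWorld <- function(seed = 1, nrow = 40, ncol = 40) {
  spec <- smallGrid(nrow, ncol)
  makeStack(spec, list(
    layerRecipe("elev", trend = "ridge", trend_range = c(1500, 4500),
                noise_sd = 300, smooth_sigma = 3),
    layerRecipe("bio11", cor_elev = -0.9, mean = 2, sd = 4, smooth_sigma = 3),
    layerRecipe("bio12", trend = "ns", trend_range = c(400, 1200),
                noise_sd = 120, smooth_sigma = 3),
    layerRecipe("noise01", trend = "flat", noise_sd = 1, smooth_sigma = 0)
  ), seed = seed)
}

# Presence/background sample matrix from a world and a true model.
smallSample <- function(stack, truth, seed = 1, n_presence = 150,
                        n_background = 800) {
  suit <- trueSuitability(stack, truth)
  occ <- sampleOccurrences(suit, n_presence, seed = seed + 100,
                           stack = stack)
  thin <- thinOccurrences(occ, stack@grid, seed = seed)
  bindSamples(extractSamples(stack, thin),
              sampleBackground(stack, n_background, seed = seed + 50))
}

# Hand-built sample matrix from plain vectors (no grid semantics).
rawSample <- function(pres, bg) {
  pres <- as.matrix(pres); bg <- as.matrix(bg)
  new("SampleMatrix",
    data = rbind(pres, bg),
    label = c(rep("presence", nrow(pres)), rep("background", nrow(bg))),
    cell = rep(NA_integer_, nrow(pres) + nrow(bg)),
    grid = smallGrid(2, 2)
  )
}

# Exhaustive grid maximization of the regularized gain for tiny problems;
# independent of the coordinate-descent path.
bruteForceGain <- function(Fl, mu, beta, lambda) {
  N <- nrow(Fl)
  eta <- as.vector(Fl %*% lambda)
  M <- max(eta)
  sum(mu * lambda) - (M + log(sum(exp(eta - M))) - log(N)) -
    sum(beta * abs(lambda))
}
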