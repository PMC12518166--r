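test_that("classification thresholds place the canonical values", {
  g <- gridSpec(1, 6, xmin = 0, ymin = 0, cellsize = 1)
  suit <- gridLayer(g, matrix(c(0.65, 0.5, 0.3, 0.1, 0.2, NA), 1, 6))
  cls <- classifySuitability(suit)
  expect_equal(values(cls)[1, 1:5], c(3L, 2L, 1L, 0L, 0L))  # 0.2 unsuitable
  expect_true(is.na(values(cls)[1, 6]))
  ## upward boundary policy at 0.4 and 0.6
  b <- classifySuitability(gridLayer(gridSpec(1, 2, 0, 0, 1),
                                     matrix(c(0.4, 0.6), 1, 2)))
  expect_equal(values(b)[1, ], c(2L, 3L))
  expect_error(classifySuitability(suit, breaks = c(0.5, 0.4, 0.6)))
})

test_that("spherical cell areas match the closed form and add up", {
  ## 1 x 1 degree cell symmetric about the equator
  g <- gridSpec(2, 1, xmin = 0, ymin = -1, cellsize = 1)
  a_north <- cellArea(g, 1)  # [0, 1] degree band
  R <- 6371.0088
  expect_equal(a_north, R^2 * (pi / 180) * (sin(pi / 180) - 0),
               tolerance = 1e-12)
  ## the equator-symmetric cell area, about 12364 km^2
  g1 <- gridSpec(1, 1, xmin = 0, ymin = -0.5, cellsize = 1)
  expect_equal(cellArea(g1, 1), R^2 * (pi / 180) * 2 * sin(0.5 * pi / 180),
               tolerance = 1e-12)
  expect_equal(round(cellArea(g1, 1)), 12364)

  ## identical-row cells share their area
  M <- cellAreaMatrix(gridSpec(3, 4, xmin = 0, ymin = 40, cellsize = 0.5))
  expect_true(all(M == M[, 1]))

  ## band additivity: adjacent bands sum to the merged band
  gfine <- gridSpec(2, 1, xmin = 0, ymin = 30, cellsize = 1)
  merged <- gridSpec(1, 1, xmin = 0, ymin = 30, cellsize = 2)
  ## merged cell is 2 deg wide too: compare per-degree-longitude slices
  expect_equal(sum(cellArea(gfine, 1:2)) * 2, cellArea(merged, 1),
               tolerance = 1e-12)
})

test_that("class areas partition the total data area", {
  g <- gridSpec(5, 5, xmin = 100, ymin = 30, cellsize = 0.25)
  set.seed(1)
  v <- matrix(runif(25), 5, 5); v[2, 3] <- NA
  cls <- classifySuitability(gridLayer(g, v))
  areas <- classAreas(cls, unit = "km2")
  total <- sum(cellAreaMatrix(g)[!is.na(v)])
  expect_equal(sum(areas$area), total, tolerance = 1e-6 * total)
  expect_equal(areas$class, c("unsuitable", "general", "moderate", "high"))
  ## empty and exhaustive classes
  all_high <- classifySuitability(gridLayer(g, matrix(0.9, 5, 5)))
  ah <- classAreas(all_high, unit = "km2")
  expect_equal(ah$area[ah$class == "high"], sum(cellAreaMatrix(g)))
  expect_equal(ah$area[ah$class == "moderate"], 0)
})

test_that("change maps do gain/loss bookkeeping and are antisymmetric", {
  g <- gridSpec(4, 4, xmin = 0, ymin = 0, cellsize = 0.5)
  mk <- function(codes) new("ClassifiedRaster", grid = g,
                            codes = matrix(as.integer(codes), 4, 4))
  cur <- mk(c(rep(1, 6), rep(0, 10)))
  fut <- mk(c(rep(0, 3), rep(1, 8), rep(0, 5)))
  same <- changeMap(cur, cur)
  expect_equal(same$summary$gained, 0)
  expect_equal(same$summary$lost, 0)
  expect_equal(same$summary$net, 0)

  cm <- changeMap(cur, fut)
  expect_equal(cm$summary$net, cm$summary$gained - cm$summary$lost)
  rev <- changeMap(fut, cur)
  expect_equal(rev$summary$gained, cm$summary$lost)
  expect_equal(rev$summary$lost, cm$summary$gained)

  ## complementary swap of equal-area (same-latitude-row) cells: net 0
  m_cur <- matrix(0L, 4, 4); m_cur[1, 1] <- 1L
  m_fut <- matrix(0L, 4, 4); m_fut[1, 2] <- 1L
  swap_cur <- new("ClassifiedRaster", grid = g, codes = m_cur)
  swap_fut <- new("ClassifiedRaster", grid = g, codes = m_fut)
  sw <- changeMap(swap_cur, swap_fut)
  expect_equal(sw$summary$net, 0)
  expect_equal(sw$summary$gained, sw$summary$lost)
  expect_gt(sw$summary$gained, 0)
})

test_that("range centroids are area-weighted cell-center means", {
  g <- gridSpec(3, 3, xmin = 99, ymin = 29, cellsize = 1)
  mk <- function(codes) new("ClassifiedRaster", grid = g,
                            codes = matrix(as.integer(codes), 3, 3))
  one <- mk(c(0, 0, 0, 0, 2, 0, 0, 0, 0))  # center cell only
  cen <- rangeCentroid(one)
  expect_equal(cen$longitude, 100.5)
  expect_equal(cen$latitude, 30.5)

  ## symmetric about the central meridian
  sym <- mk(c(0, 0, 0, 1, 0, 1, 0, 0, 0))
  expect_equal(rangeCentroid(sym)$longitude, 100.5)

  ## two equal-latitude equal-area cells at lon 100.5 and 102.5 -> 101.5
  g2 <- gridSpec(1, 3, xmin = 100, ymin = 30, cellsize = 1)
  two <- new("ClassifiedRaster", grid = g2,
             codes = matrix(c(1L, 0L, 1L), 1, 3))
  expect_equal(rangeCentroid(two)$longitude, 101.5)

  none <- mk(rep(0, 9))
  nr <- rangeCentroid(none)
  expect_equal(nr$n_cells, 0L)
  expect_true(is.na(nr$longitude))
})

test_that("centroid shifts use haversine distance and compass octants", {
  a <- data.frame(longitude = 103, latitude = 31)
  same <- centroidShift(a, a)
  expect_equal(same$distance_km, 0)
  expect_equal(same$octant, "none")

  north <- centroidShift(a, data.frame(longitude = 103, latitude = 32))
  expect_equal(north$distance_km, 111.1951, tolerance = 1e-4)
  expect_equal(north$octant, "N")

  ne <- centroidShift(a, data.frame(longitude = 103.8, latitude = 31.7))
  expect_equal(ne$octant, "NE")
  sw <- centroidShift(a, data.frame(longitude = 102.2, latitude = 30.3))
  expect_equal(sw$octant, "SW")
  expect_error(centroidShift(a, data.frame(longitude = NA, latitude = 1)),
               "no range")
})
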