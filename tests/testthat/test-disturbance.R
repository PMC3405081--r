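test_that("land-cover mask equals the per-cell indicator", {
  lc <- rasterGrid(matrix(c(82, 71, 11, 82, 82, 71, 11, 71, 82), 3, 3),
                   cellSize = 100)
  m <- landcoverMask(lc, 82L)
  expect_equal(gridValues(m),
               matrix(as.double(gridValues(lc) == 82), 3, 3))
  # uniform cropland, cropland in codes -> all ones
  uni <- rasterGrid(matrix(82, 4, 4))
  expect_true(all(gridValues(landcoverMask(uni, c(82L, 21L))) == 1))
  # empty code set -> all zeros
  expect_true(all(gridValues(landcoverMask(uni, integer())) == 0))
  # unknown code refused
  expect_error(landcoverMask(uni, 999L), "schema")
  # nodata propagates
  v <- gridValues(lc); v[2, 2] <- NA
  m2 <- landcoverMask(rasterGrid(v), 82L)
  expect_true(is.na(gridValues(m2)[2, 2]))
})

test_that("topographic-change mask applies per-cover thresholds exactly", {
  set.seed(1)
  lc <- rasterGrid(matrix(sample(c(82L, 71L, 41L), 64, TRUE), 8, 8))
  topo <- rasterGrid(matrix(runif(64, 0, 25), 8, 8))
  thr <- c("82" = 10.21, "71" = 14.0, "41" = 17.57)
  m <- topoChangeMask(topo, lc, thr)
  # brute-force per-cell comparison
  for (i in 1:8) for (j in 1:8) {
    expected <- as.double(abs(gridValues(topo)[i, j]) >=
                            thr[as.character(gridValues(lc)[i, j])])
    expect_identical(gridValues(m)[i, j], unname(expected))
  }
  # all-zero change -> all-zero mask
  z <- rasterGrid(matrix(0, 8, 8))
  expect_true(all(gridValues(topoChangeMask(z, lc, thr)) == 0))
  # single cell at 12.0 m vs threshold 10.21 -> flagged
  v <- matrix(0, 8, 8); v[3, 3] <- 12
  lcu <- rasterGrid(matrix(82L, 8, 8))
  m2 <- topoChangeMask(rasterGrid(v), lcu, c("82" = 10.21))
  expect_equal(sum(gridValues(m2)), 1)
  expect_equal(gridValues(m2)[3, 3], 1)
  # missing threshold for an encountered cover is a configuration error
  expect_error(topoChangeMask(topo, lc, c("82" = 10.21)), "threshold")
})

test_that("well-field density equals the direct summation oracle", {
  tpl <- rasterGrid(matrix(0, 64, 64), cellSize = 100)
  set.seed(8)
  for (s in 1:3) {
    nw <- sample(3:50, 1)
    xy <- cbind(runif(nw, 0, 6400), runif(nw, 0, 6400))
    wells <- pointSet(xy)
    dens <- wellDensity(wells, tpl, bandwidth = 900)
    expect_equal(gridValues(dens), kdeOracle(xy, tpl, 900), tolerance = 1e-10)
  }
  # zero wells -> all-zero mask
  m0 <- wellFieldMask(featureSet("point"), tpl, 1000, 0)
  expect_true(all(gridValues(m0) == 0))
  # one well, near-zero threshold -> a disk of radius = bandwidth
  one <- pointSet(cbind(3200, 3200))
  m1 <- wellFieldMask(one, tpl, 1000, 1e-9)
  cc <- cellCenters(tpl)
  d <- sqrt((cc$x - 3200)^2 + (cc$y - 3200)^2)
  disagree <- gridValues(m1) != as.double(d < 1000)
  # within one cell of the rim only
  expect_true(all(abs(d[disagree] - 1000) <= 100 * sqrt(2)))
  # density integrates to ~n over the plane (interior well, full support)
  expect_equal(sum(gridValues(wellDensity(one, tpl, 1000))) *
                 cellAreaKm2(tpl), 1, tolerance = 1e-3)
})

test_that("a higher density threshold yields a subset mask", {
  tpl <- rasterGrid(matrix(0, 48, 48), cellSize = 100)
  set.seed(21)
  wells <- pointSet(cbind(runif(30, 0, 4800), runif(30, 0, 4800)))
  m1 <- wellFieldMask(wells, tpl, 1000, 0.5)
  m2 <- wellFieldMask(wells, tpl, 1000, 2)
  expect_true(all(gridValues(m2) <= gridValues(m1)))
})

test_that("linear mask hits every cell the line crosses", {
  tpl <- rasterGrid(matrix(0, 32, 32), cellSize = 100)
  # horizontal line through the middle of row 10
  y <- gridBounds(tpl)["ymax"] - 9.5 * 100
  ln <- featureSet("line", list(cbind(c(0, 3200), c(y, y))))
  m <- linearMask(ln, tpl, resolution = 25)
  expect_true(all(gridValues(m)[10, ] == 1))
  expect_equal(sum(gridValues(m)), 32)
  # empty set -> all zeros
  expect_true(all(gridValues(linearMask(featureSet("line"), tpl)) == 0))
  # random polylines vs point-sampling oracles: every cell the res/4
  # sampler finds must be marked, and a res/64 sampler (fine enough to
  # resolve corner clips shorter than the coarse step) must agree exactly
  sampleHits <- function(verts, step) {
    hit <- matrix(FALSE, 32, 32)
    for (i in seq_len(nrow(verts) - 1)) {
      L <- sqrt(sum((verts[i + 1, ] - verts[i, ])^2))
      t <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
      px <- verts[i, 1] + t * (verts[i + 1, 1] - verts[i, 1])
      py <- verts[i, 2] + t * (verts[i + 1, 2] - verts[i, 2])
      idx <- pointToCell(tpl, px, py)
      ok <- !is.na(idx$row)
      hit[cbind(idx$row[ok], idx$col[ok])] <- TRUE
    }
    hit
  }
  set.seed(5)
  for (rep in 1:5) {
    verts <- cbind(runif(6, 0, 3200), runif(6, 0, 3200))
    m <- gridValues(linearMask(featureSet("line", list(verts)), tpl,
                               resolution = 25))
    coarse <- sampleHits(verts, 25 / 4)
    expect_true(all(m[coarse] == 1))
    expect_equal(m, matrix(as.double(sampleHits(verts, 25 / 64)), 32, 32))
  }
})

test_that("point-buffer mask equals the per-cell Euclidean check", {
  tpl <- rasterGrid(matrix(0, 20, 20), cellSize = 100)
  pt <- pointSet(cbind(950, 950))
  m <- pointBufferMask(pt, tpl, 300)
  cc <- cellCenters(tpl)
  expect_equal(gridValues(m),
               matrix(as.double(sqrt((cc$x - 950)^2 + (cc$y - 950)^2) <= 300),
                      20, 20))
  # radius 0 -> only the cell containing the point
  m0 <- pointBufferMask(pt, tpl, 0)
  expect_equal(sum(gridValues(m0)), 1)
  # union of two singleton buffers equals the two-point mask
  two <- pointSet(rbind(c(500, 500), c(700, 700)))
  mu <- unionMasks(list(pointBufferMask(pointSet(cbind(500, 500)), tpl, 300),
                        pointBufferMask(pointSet(cbind(700, 700)), tpl, 300)))
  expect_equal(gridValues(pointBufferMask(two, tpl, 300)), gridValues(mu))
})

test_that("mask union is a commutative, idempotent cellwise OR", {
  set.seed(9)
  a <- randomMask(16, 16); b <- randomMask(16, 16); z <- mkMask(matrix(0, 16, 16))
  expect_equal(gridValues(unionMasks(list(a, z))), gridValues(a))
  expect_equal(gridValues(unionMasks(list(a, b))),
               gridValues(unionMasks(list(b, a))))
  expect_equal(gridValues(unionMasks(list(a, a))), gridValues(a))
  # disjoint indicators: cardinality adds
  m1 <- matrix(0, 8, 8); m1[1:10] <- 1
  m2 <- matrix(0, 8, 8); m2[21:30] <- 1
  u <- unionMasks(list(mkMask(m1), mkMask(m2)))
  expect_equal(sum(gridValues(u)), 20)
  # misaligned grids refused
  expect_error(unionMasks(list(a, randomMask(8, 8))), "alignment")
})

test_that("nodata in one source behaves as 0, all-nodata stays nodata", {
  tpl <- rasterGrid(matrix(0, 2, 2))
  a <- binaryMask(matrix(c(1, NA, NA, 0), 2, 2), tpl)
  b <- binaryMask(matrix(c(NA, 1, NA, 0), 2, 2), tpl)
  u <- unionMasks(list(a, b))
  expect_equal(gridValues(u)[1, 1], 1)  # 1 | NA
  expect_equal(gridValues(u)[2, 1], 1)  # NA | 1
  expect_true(is.na(gridValues(u)[1, 2]))  # NA | NA
  expect_equal(gridValues(u)[2, 2], 0)
})

test_that("adding a source layer never unsets a disturbed cell", {
  set.seed(3)
  lc <- rasterGrid(matrix(sample(c(82L, 71L, 11L), 32^2, TRUE), 32, 32),
                   cellSize = 100)
  wells <- pointSet(cbind(runif(20, 0, 3200), runif(20, 0, 3200)))
  base <- disturbanceMask(lc, config = disturbanceConfig())
  more <- disturbanceMask(lc, wells = wells, config = disturbanceConfig())
  expect_true(all(gridValues(more) >= gridValues(base), na.rm = TRUE))
})
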