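test_that("landscapes are bit-identical for a fixed seed", {
  p <- landscapeParams(gridShape = c(48, 48), seed = 11, nWells = 60)
  a <- generateLandscape(p)
  b <- generateLandscape(p)
  expect_identical(gridValues(a@landcover), gridValues(b@landcover))
  expect_identical(gridValues(a@wpc), gridValues(b@wpc))
  expect_identical(pointCoords(a@wells), pointCoords(b@wells))
  expect_identical(featureAttrs(a@craneObs), featureAttrs(b@craneObs))
  expect_identical(a@craneSiteTruth, b@craneSiteTruth)
  # a different seed changes the realization
  c <- generateLandscape(landscapeParams(gridShape = c(48, 48), seed = 12,
                                         nWells = 60))
  expect_false(identical(gridValues(a@landcover), gridValues(c@landcover)))
})

test_that("degenerate class proportions give a uniform land cover", {
  p <- landscapeParams(gridShape = c(32, 32), seed = 1,
                       classProportions = c("82" = 1.0))
  ls <- generateLandscape(p)
  expect_true(all(gridValues(ls@landcover) == 82))
})

test_that("invalid parameters are refused naming the offending field", {
  expect_error(landscapeParams(classProportions = c("82" = 0.5)),
               "classProportions")
  expect_error(landscapeParams(gridShape = c(0, 10)), "gridShape")
  expect_error(landscapeParams(wpcRange = c(0, 7)), "wpcRange")
  expect_error(landscapeParams(cellSizeM = -5), "cellSizeM")
})

test_that("realized class fractions track targets and wind is autocorrelated", {
  p <- landscapeParams(seed = 5)   # default 256 x 256
  ls <- generateLandscape(p)
  frac <- table(gridValues(ls@landcover)) / prod(gridDims(ls@landcover))
  target <- p@classProportions
  for (code in names(target))
    expect_lt(abs(frac[[code]] - target[[code]]), 0.05)
  expect_gt(moransI(gridValues(ls@wpc)), 0)
  expect_true(all(gridValues(ls@wpc) %in% 1:7))
})

test_that("clustered wells are closer together than uniform points", {
  # Monte-Carlo comparison over 100 seeds: mean nearest-neighbor distance
  # of the Thomas-process wells vs a uniform point set of equal size
  nnClustered <- nnUniform <- numeric(100)
  for (s in 1:100) {
    ls <- generateLandscape(landscapeParams(
      gridShape = c(256, 256), cellSizeM = 100, seed = s,
      nWells = 500, wellClusterSd = 2000,
      nCraneSites = 1L, nTurbinesExisting = 1L, nTurbinesProposed = 1L,
      nHamlets = 1L, nPriorityPolygons = 1L))
    xy <- pointCoords(ls@wells)
    set.seed(s + 7e6)
    uni <- cbind(runif(500, 0, 25600), runif(500, 0, 25600))
    nnClustered[s] <- meanNNDist(xy)
    nnUniform[s] <- meanNNDist(uni)
  }
  expect_lt(mean(nnClustered), mean(nnUniform))
  # clustering wins in the overwhelming majority of realizations too
  expect_gt(mean(nnClustered < nnUniform), 0.95)
})

test_that("crane histories ship sound ground-truth labels", {
  expect_error(generateCraneHistory(0, 2010), "nSites")
  expect_error(generateCraneHistory(3, integer()), "years")
  ch <- generateCraneHistory(10, 2008:2012, seed = 3)
  expect_s4_class(ch$observations, "FeatureSet")
  expect_equal(nrow(ch$truth), 10)
  # both label classes occur
  expect_true(any(ch$truth$repeated) && any(!ch$truth$repeated))
  # labels re-derivable from the dates: >=2 years or >=3 days in one year
  a <- featureAttrs(ch$observations)
  for (s in ch$truth$site_id) {
    d <- as.Date(a$date[a$site_id == s])
    yrs <- as.integer(format(d, "%Y"))
    manual <- length(unique(yrs)) >= 2 ||
      any(tapply(d, yrs, function(x) length(unique(x))) >= 3)
    expect_identical(manual, ch$truth$repeated[ch$truth$site_id == s])
  }
})

test_that("all generated vector features lie inside the grid bounds", {
  for (s in c(2, 17)) {
    ls <- generateLandscape(landscapeParams(gridShape = c(64, 64), seed = s))
    b <- gridBounds(ls@landcover)
    for (nm in c("wells", "hamlets", "craneObs", "turbines", "roads",
                 "rivers", "priorityPolygons", "protectedAreas")) {
      for (g in featureCoords(slot(ls, nm))) {
        expect_true(all(g[, 1] >= b["xmin"] & g[, 1] <= b["xmax"]))
        expect_true(all(g[, 2] >= b["ymin"] & g[, 2] <= b["ymax"]))
      }
    }
  }
})

test_that("per-layer substreams isolate layers from parameter changes", {
  a <- generateLandscape(landscapeParams(gridShape = c(48, 48), seed = 4,
                                         nWells = 50))
  b <- generateLandscape(landscapeParams(gridShape = c(48, 48), seed = 4,
                                         nWells = 200))
  # changing the well count leaves the land-cover realization untouched
  expect_identical(gridValues(a@landcover), gridValues(b@landcover))
  expect_identical(gridValues(a@wpc), gridValues(b@wpc))
})
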