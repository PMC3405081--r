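test_that("repeated-stopover rule implements both qualifying clauses", {
  mkObs <- function(dates, xy = cbind(1000, 1000)) {
    n <- length(dates)
    pointSet(xy[rep(1, n), , drop = FALSE], data.frame(date = dates))
  }
  # observations in two distinct years -> repeated
  expect_equal(nFeatures(repeatedStopoverSites(
    mkObs(c("2010-05-01", "2012-04-30")), 500)), 1)
  # three distinct days in one year -> repeated
  expect_equal(nFeatures(repeatedStopoverSites(
    mkObs(c("2011-04-01", "2011-04-02", "2011-04-03")), 500)), 1)
  # two days in one year -> not repeated
  expect_equal(nFeatures(repeatedStopoverSites(
    mkObs(c("2011-04-01", "2011-04-02")), 500)), 0)
  # three observations but only two distinct days -> not repeated
  expect_equal(nFeatures(repeatedStopoverSites(
    mkObs(c("2011-04-01", "2011-04-02", "2011-04-02")), 500)), 0)
  # undated observation is a data error naming the record
  bad <- pointSet(rbind(c(0, 0), c(10, 10)),
                  data.frame(date = c("2011-04-01", "not-a-date")))
  expect_error(repeatedStopoverSites(bad, 500), "record\\(s\\) 2")
})

test_that("stopover clustering separates distant sites", {
  # two sites 5 km apart: one qualifying, one not
  obs <- pointSet(rbind(c(0, 0), c(30, 10), c(10, 25),
                        c(5000, 5000), c(5010, 5010)),
                  data.frame(date = c("2011-04-01", "2011-04-02",
                                      "2011-04-03",
                                      "2012-04-01", "2012-04-02")))
  sites <- repeatedStopoverSites(obs, 500)
  expect_equal(nFeatures(sites), 1)
  xy <- pointCoords(sites)
  expect_lt(sqrt(sum((xy - c(13.33, 11.67))^2)), 1)
})

test_that("stopover recovery matches generator ground truth exactly", {
  for (s in c(1, 5, 42, 1234)) {
    ch <- generateCraneHistory(12, 2008:2012, seed = s)
    sites <- repeatedStopoverSites(ch$observations, 500)
    expect_equal(nFeatures(sites), sum(ch$truth$repeated))
    if (nFeatures(sites) > 0) {
      # every recovered site sits at a true repeated site
      xy <- pointCoords(sites)
      truthXY <- ch$truth[ch$truth$repeated, c("x", "y")]
      for (i in seq_len(nrow(xy))) {
        d <- sqrt((truthXY$x - xy[i, 1])^2 + (truthXY$y - xy[i, 2])^2)
        expect_lt(min(d), 200)
      }
    }
  }
})

test_that("category and density rules match enumeration", {
  tpl <- rasterGrid(matrix(0, 6, 6), cellSize = 100)
  sens <- rasterGrid(matrix(rep(1:6, 6), 6, 6), cellSize = 100)
  layers <- list(sensitivity = sens)
  m <- compileRule(exclusionRule("ne_top4", "sensitivity", "category_in_set",
                                 categories = 3:6), layers, tpl)
  expect_equal(gridValues(m),
               matrix(as.double(gridValues(sens) %in% 3:6), 6, 6))
  expect_identical(provenance(m), "ne_top4")
  # boundary-inclusive density threshold ("or greater")
  wf <- rasterGrid(matrix(104, 6, 6), cellSize = 100)
  md <- compileRule(exclusionRule("wf", "waterfowl", "density_at_least",
                                  threshold = 104),
                    list(waterfowl = wf), tpl)
  expect_true(all(gridValues(md) == 1))
  # polygon burn on an empty polygon set -> all zeros
  mp <- compileRule(exclusionRule("p", "polys", "polygon_burn"),
                    list(polys = featureSet("polygon")), tpl)
  expect_true(all(gridValues(mp) == 0))
  # category rule on polygons with a category attribute
  ring <- cbind(c(50, 350, 350, 50), c(50, 50, 350, 350))
  zones <- featureSet("polygon", list(ring), data.frame(category = 5))
  mz <- compileRule(exclusionRule("z", "zones", "category_in_set",
                                  categories = 3:6),
                    list(zones = zones), tpl)
  expect_gt(sum(gridValues(mz)), 0)
  # missing layer and type mismatch are configuration errors
  expect_error(compileRule(exclusionRule("x", "absent", "polygon_burn"),
                           layers, tpl), "not provided")
  expect_error(compileRule(exclusionRule("x", "sensitivity", "polygon_burn"),
                           layers, tpl), "polygon")
})

test_that("line and point buffers are monotone in radius", {
  tpl <- rasterGrid(matrix(0, 24, 24), cellSize = 100)
  ln <- featureSet("line", list(cbind(c(0, 2400), c(1200, 1300))))
  m1 <- lineBufferMask(ln, tpl, 200)
  m2 <- lineBufferMask(ln, tpl, 600)
  expect_true(all(gridValues(m2) >= gridValues(m1)))
  pt <- pointSet(cbind(1200, 1200))
  expect_true(all(gridValues(pointBufferMask(pt, tpl, 800)) >=
                    gridValues(pointBufferMask(pt, tpl, 300))))
})

test_that("composed exclusions equal the union of singleton compilations", {
  ls <- generateLandscape(landscapeParams(gridShape = c(64, 64), seed = 6))
  layers <- landscapeLayers(ls)
  tpl <- ls@landcover
  rs <- shippedRuleSet("nd_sd")
  composed <- composeExclusions(rs, layers, tpl)
  singles <- lapply(rules(rs), compileRule, layers = layers, template = tpl)
  expect_equal(gridValues(composed), gridValues(unionMasks(singles)))
  # provenance carries every rule id
  expect_setequal(provenance(composed),
                  vapply(rules(rs), function(r) r@ruleId, character(1)))
  # order independence
  rev_rs <- ruleSet(jurisdiction(rs), rev(rules(rs)))
  expect_equal(gridValues(composeExclusions(rev_rs, layers, tpl)),
               gridValues(composed))
  # empty ruleset -> all-zeros
  expect_true(all(gridValues(composeExclusions(ruleSet("empty"), layers,
                                               tpl)) == 0))
  # single rule equals compileRule
  one <- ruleSet("one", rules(rs)[1])
  expect_equal(gridValues(composeExclusions(one, layers, tpl)),
               gridValues(singles[[1]]))
  # a failing rule aborts naming its id
  badRs <- ruleSet("bad", list(exclusionRule("bad_rule", "nope",
                                             "polygon_burn")))
  expect_error(composeExclusions(badRs, layers, tpl), "bad_rule")
})

test_that("shipped rule sets round-trip through YAML losslessly", {
  for (nm in c("ab_sk", "mt", "ne", "nd_sd", "wy")) {
    rs <- shippedRuleSet(nm)
    expect_gt(length(rules(rs)), 0)
    tmp <- tempfile(fileext = ".yaml")
    writeRuleSet(rs, tmp)
    back <- readRuleSet(tmp)
    expect_identical(jurisdiction(back), jurisdiction(rs))
    expect_equal(length(rules(back)), length(rules(rs)))
    for (i in seq_along(rules(rs))) {
      a <- rules(rs)[[i]]; b <- rules(back)[[i]]
      expect_identical(a@ruleId, b@ruleId)
      expect_identical(a@source, b@source)
      expect_identical(a@operator, b@operator)
      expect_equal(a@params, b@params)
    }
  }
  # duplicate rule ids are rejected
  expect_error(ruleSet("dup", list(exclusionRule("a", "x", "polygon_burn"),
                                   exclusionRule("a", "y", "polygon_burn"))),
               "unique")
})
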