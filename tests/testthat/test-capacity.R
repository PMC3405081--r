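test_that("capacity-density lookup returns the published MW/km2", {
  tab <- capacityDensityTable()
  expect_identical(capacityDensity(3, tab), 4.3)
  expect_identical(capacityDensity(4, tab), 4.8)
  expect_identical(capacityDensity(5, tab), 5.2)
  expect_identical(capacityDensity(6, tab), 5.5)
  expect_identical(capacityDensity(7, tab), 6.0)
  expect_identical(capacityDensity(1, tab), 0)
  expect_identical(capacityDensity(2, tab), 0)
  expect_error(capacityDensity(8, tab), "\\[1, 7\\]")
  expect_error(capacityDensity(0, tab), "\\[1, 7\\]")
  # densities must increase strictly with class
  expect_error(capacityDensityTable(c("3" = 5, "4" = 4)), "increasing")
})

test_that("10 km2 of class-4 wind carries 0.048 GW", {
  # 100 m cells: 1000 cells = 10 km2, all class 4, one region
  m <- matrix(0, 40, 40); m[1:25, 1:40] <- 1
  mask <- mkMask(m)
  wpc <- rasterGrid(matrix(4, 40, 40), cellSize = 100)
  reg <- rasterGrid(matrix(1, 40, 40), cellSize = 100)
  out <- aggregateCapacity(mask, wpc, reg, regionNames = "only")
  expect_equal(out$low_impact_gw, 10 * 4.8 / 1000)
  # empty mask -> no capacity anywhere
  none <- aggregateCapacity(mkMask(matrix(0, 40, 40)), wpc, reg)
  expect_equal(sum(none$low_impact_gw), 0)
})

test_that("regional aggregation equals the per-cell summation oracle", {
  set.seed(19)
  for (rep in 1:100) {
    mask <- randomMask(32, 32, 0.4)
    wpc <- rasterGrid(matrix(sample(1:7, 32^2, TRUE), 32, 32),
                      cellSize = 100)
    reg <- rasterGrid(matrix(sample(1:3, 32^2, TRUE), 32, 32),
                      cellSize = 100)
    out <- aggregateCapacity(mask, wpc, reg)
    dens <- c(0, 0, 4.3, 4.8, 5.2, 5.5, 6.0)
    for (r in 1:3) {
      sel <- gridValues(mask) == 1 & gridValues(reg) == r
      oracle <- sum(0.01 * dens[gridValues(wpc)[sel]]) / 1000
      expect_equal(out$low_impact_gw[out$region == as.character(r)], oracle)
    }
  }
})

test_that("low-impact cells without wind class count as zero capacity", {
  m <- matrix(1, 4, 4)
  w <- matrix(5, 4, 4); w[1, 1] <- NA
  out <- suppressMessages(
    aggregateCapacity(mkMask(m), rasterGrid(w, cellSize = 100),
                      rasterGrid(matrix(1, 4, 4), cellSize = 100)))
  expect_equal(out$low_impact_gw, 15 * 0.01 * 5.2 / 1000)
  expect_equal(attr(out, "n_nodata_wpc"), 1)
})

test_that("percent-of-goal arithmetic reproduces the published rows", {
  expect_identical(percentOfGoal(139, 5.26), 2643L)
  expect_identical(percentOfGoal(254, 2.26), 11239L)
  expect_identical(percentOfGoal(137, 1.10), 12455L)
  expect_identical(percentOfGoal(5, 5), 100L)
  expect_error(percentOfGoal(1, 0), "goalGw")
})

test_that("region summary totals sum goals and GW before the percent", {
  t1 <- ngpCapacityInputs()
  expect_equal(sum(t1$goal_gw), 29.95)
  expect_equal(sum(t1$low_impact_gw), 1056)
  s <- summarizeRegions(t1[, c("region", "low_impact_gw")],
                        t1[, c("region", "goal_gw")])
  tot <- s[s$region == "Total", ]
  expect_equal(tot$goal_gw, 29.95)
  expect_equal(tot$low_impact_gw, 1056)
  expect_identical(tot$pct_of_goal, 3526L)
  # single region: total equals the region's own row
  one <- summarizeRegions(data.frame(region = "a", low_impact_gw = 7),
                          data.frame(region = "a", goal_gw = 2))
  expect_equal(one$low_impact_gw, c(7, 7))
  expect_identical(one$pct_of_goal, c(350L, 350L))
  # a region without a goal is a configuration error
  expect_error(summarizeRegions(data.frame(region = "x", low_impact_gw = 1),
                                data.frame(region = "y", goal_gw = 1)),
               "goal")
})
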