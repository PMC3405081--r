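test_that("connectivity convention decides diagonal adjacency", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  mask <- mkMask(m)
  expect_equal(nrow(labelPatches(mask, 8)$table), 1)
  expect_equal(nrow(labelPatches(mask, 4)$table), 2)
  # empty mask -> empty table
  expect_equal(nrow(labelPatches(mkMask(matrix(0, 3, 3)))$table), 0)
})

test_that("patch labeling agrees with a flood-fill oracle", {
  set.seed(31)
  for (rep in 1:10) {
    mask <- randomMask(32, 32, p = runif(1, 0.2, 0.7))
    for (conn in c(4, 8)) {
      got <- labelPatches(mask, conn)
      ref <- floodFillLabel(gridValues(mask), conn)
      expect_equal(max(got$labels@values), max(ref))
      # same partition: labels are a relabeling of the oracle's
      expect_equal(length(unique(paste(got$labels@values, ref))),
                   max(ref) + (any(gridValues(mask) == 0)))
      expect_equal(sort(got$table$cell_count),
                   sort(as.integer(table(ref[ref > 0]))))
    }
  }
})

test_that("patch labeling agrees with an external image-labeling routine", {
  skip_if_not_installed("EBImage")
  set.seed(13)
  mask <- randomMask(40, 40, 0.45)
  got <- labelPatches(mask, 4)
  ref <- EBImage::bwlabel(gridValues(mask))
  expect_equal(max(got$labels@values), max(ref))
})

test_that("patch filter keeps large patches and close small ones", {
  # 100 m cells: a 150-cell (1.5 km2) anchor, a 50-cell (0.5 km2) patch at
  # 600 m center distance (kept), a 50-cell patch ~3.7 km away (removed)
  m <- matrix(0, 64, 64)
  m[10:24, 10:19] <- 1            # 150 cells, anchor
  m[10:19, 25:29] <- 1            # 50 cells; centers 6 cells apart -> 600 m
  m[50:59, 45:49] <- 1            # 50 cells, far from the anchor
  mask <- mkMask(m)
  out <- filterSmallIsolated(mask, 1, 800, 8)
  expect_true(all(gridValues(out)[10:24, 10:19] == 1))
  expect_true(all(gridValues(out)[10:19, 25:29] == 1))
  expect_true(all(gridValues(out)[50:59, 45:49] == 0))
  expect_equal(gridValues(out), patchFilterOracle(mask, 1, 800, 8))
  # a single 2 km2 patch passes untouched
  big <- matrix(0, 64, 64); big[1:20, 1:10] <- 1
  expect_equal(gridValues(filterSmallIsolated(mkMask(big))), big)
})

test_that("patch filter equals the all-pairs-distance oracle on random masks", {
  set.seed(77)
  for (rep in 1:25) {
    mask <- randomMask(48, 48, p = runif(1, 0.1, 0.5))
    out <- filterSmallIsolated(mask, 1, 800, 8)
    expect_equal(gridValues(out), patchFilterOracle(mask, 1, 800, 8))
  }
})

test_that("patch filter is idempotent and output is a subset of input", {
  set.seed(55)
  for (rep in 1:5) {
    mask <- randomMask(40, 40, 0.35)
    once <- filterSmallIsolated(mask, 1, 800, 8)
    twice <- filterSmallIsolated(once, 1, 800, 8)
    expect_true(all(gridValues(once) <= gridValues(mask)))
    expect_equal(gridValues(twice), gridValues(once))
  }
})

test_that("an infinite isolation threshold keeps all patches when an anchor exists", {
  m <- matrix(0, 32, 32)
  m[1:10, 1:10] <- 1              # 100 cells = 1 km2 anchor (>= reading)
  m[30, 30] <- 1                  # lone far cell
  out <- filterSmallIsolated(mkMask(m), 1, Inf, 8)
  expect_equal(gridValues(out), m)
  # without any anchor, small isolated patches are removed
  m2 <- matrix(0, 32, 32); m2[5, 5] <- 1
  out2 <- filterSmallIsolated(mkMask(m2), 1, Inf, 8)
  expect_true(all(gridValues(out2) == 0))
})

test_that("patches of exactly the threshold area are retained as anchors", {
  # 100 cells at 100 m = exactly 1 km2
  m <- matrix(0, 32, 32); m[1:10, 1:10] <- 1
  out <- filterSmallIsolated(mkMask(m), 1, 0, 8)
  expect_equal(sum(gridValues(out)), 100)
})
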