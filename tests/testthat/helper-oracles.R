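# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: labeling is a stack flood fill, the
# kernel density a double loop, the patch filter an all-pairs distance scan.

mkMask <- function(m, cellSizeM = 100) {
  tpl <- rasterGrid(matrix(0, nrow(m), ncol(m)), cellSize = cellSizeM)
  binaryMask(m == 1, tpl)
}

randomMask <- function(nr, nc, p = 0.5, cellSizeM = 100) {
  mkMask(matrix(rbinom(nr * nc, 1, p), nr, nc), cellSizeM)
}

# stack-based flood fill labeling (4- or 8-connectivity)
floodFillLabel <- function(m, connectivity = 8) {
  d <- dim(m)
  lab <- matrix(0L, d[1], d[2])
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  nextLab <- 0L
  for (start in which(m == 1)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    stack <- start
    lab[start] <- nextLab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% d[1] + 1L
      c <- (cur - 1L) %/% d[1] + 1L
      for (k in seq_len(nrow(nbr))) {
        rr <- r + nbr[k, 1]; cc <- c + nbr[k, 2]
        if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2] &&
            m[rr, cc] == 1 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextLab
          stack <- c(stack, (cc - 1L) * d[1] + rr)
        }
      }
    }
  }
  lab
}

# O(cells x wells) direct quartic-kernel summation, wells per km2
kdeOracle <- function(xy, template, bandwidth) {
  d <- gridDims(template)
  cs <- cellSize(template)
  b <- gridBounds(template)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    cy <- b["ymax"] - (i - 0.5) * cs
    for (j in seq_len(d[2])) {
      cx <- b["xmin"] + (j - 0.5) * cs
      s <- 0
      for (k in seq_len(nrow(xy))) {
        dist2 <- (cx - xy[k, 1])^2 + (cy - xy[k, 2])^2
        if (dist2 <= bandwidth^2) {
          u <- 1 - dist2 / bandwidth^2
          s <- s + 3 / (pi * bandwidth^2) * u^2
        }
      }
      out[i, j] <- s * 1e6
    }
  }
  out
}

# all-pairs-distance patch filter oracle: flood fill, areas, then for every
# small patch scan every (small cell, large cell) pair
patchFilterOracle <- function(mask, minKm2 = 1, maxDist = 800,
                              connectivity = 8) {
  m <- gridValues(mask)
  m[is.na(m)] <- 0
  cs <- cellSize(mask)
  lab <- floodFillLabel(m, connectivity)
  cc <- cellCenters(mask)
  areas <- table(lab[lab > 0]) * (cs / 1000)^2
  large <- as.integer(names(areas)[areas >= minKm2])
  keep <- large
  small <- setdiff(as.integer(names(areas)), large)
  if (length(large)) {
    lx <- cc$x[lab %in% large]; ly <- cc$y[lab %in% large]
    for (p in small) {
      px <- cc$x[lab == p]; py <- cc$y[lab == p]
      dmin <- Inf
      for (i in seq_along(px))
        dmin <- min(dmin, sqrt((lx - px[i])^2 + (ly - py[i])^2))
      if (dmin <= maxDist) keep <- c(keep, p)
    }
  }
  out <- matrix(as.double(lab %in% keep & lab > 0), nrow(m), ncol(m))
  out[is.na(gridValues(mask))] <- NA_real_
  out
}

# mean nearest-neighbor distance of a point matrix
meanNNDist <- function(xy) {
  n <- nrow(xy)
  mean(vapply(seq_len(n), function(i) {
    d <- sqrt((xy[-i, 1] - xy[i, 1])^2 + (xy[-i, 2] - xy[i, 2])^2)
    min(d)
  }, numeric(1)))
}
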