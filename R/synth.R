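#' @include turbines.R
NULL

# run expr under a fixed seed, then restore the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# independent per-layer substream: one global seed + a fixed layer offset
layerSeed <- function(seed, k) (abs(seed) * 131 + k * 7919) %% 2147483647

#' Smoothed standardized Gaussian random field
#'
#' White noise circularly convolved with an isotropic Gaussian kernel of
#' standard deviation \code{corrCells} (in cells) via FFT, then
#' standardized to zero mean and unit variance. The workhorse behind the
#' neutral-landscape layers: thresholding such a field at quantiles yields
#' contiguous patches with a controllable characteristic scale.
#'
#' @param nr,nc grid dimensions.
#' @param corrCells kernel standard deviation in cells (0 = pure noise).
#' @return an \code{nr} by \code{nc} numeric matrix.
#' @export
gaussianField <- function(nr, nc, corrCells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corrCells > 1e-8) {
    wrapDist <- function(n) { i <- 0:(n - 1); pmin(i, n - i) }
    k <- exp(-outer(wrapDist(nr)^2, wrapDist(nc)^2, `+`) /
               (2 * corrCells^2))
    k <- k / sum(k)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
      (nr * nc)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Moran's I spatial autocorrelation at lag one cell
#'
#' Rook-neighbor Moran's I of a numeric matrix; positive values indicate
#' that adjacent cells are more alike than chance.
#'
#' @param m numeric matrix.
#' @return scalar Moran's I.
#' @export
moransI <- function(m) {
  z <- m - mean(m)
  num <- 0; W <- 0
  for (s in list(c(0, 1), c(1, 0))) {
    a <- z[seq_len(nrow(z) - s[1]), seq_len(ncol(z) - s[2])]
    b <- z[seq_len(nrow(z) - s[1]) + s[1], seq_len(ncol(z) - s[2]) + s[2]]
    num <- num + 2 * sum(a * b)
    W <- W + 2 * length(a)
  }
  (length(z) / W) * num / sum(z^2)
}

#' Parameters of the synthetic-landscape generator
#'
#' Defaults describe a 25.6 km x 25.6 km study window at 100 m resolution
#' in a cropland-dominated northern-plains landscape.
#'
#' @param gridShape c(rows, cols) cells.
#' @param cellSizeM cell side, meters.
#' @param seed integer master seed; each layer draws from an independent
#'   substream derived from it.
#' @param classProportions named numeric, land-cover code -> target areal
#'   fraction (must sum to 1).
#' @param lcPatchScale characteristic land-cover patch size, meters.
#' @param nWells well count; \code{wellClusterSd} is the Thomas-process
#'   cluster spread, meters.
#' @param wellClusterSd cluster standard deviation, meters.
#' @param nHamlets settlement count.
#' @param wpcRange c(min, max) wind power classes generated.
#' @param wpcCorrLength correlation length of the wind-class field, meters.
#' @param nCraneSites crane stopover site count.
#' @param craneObsPerSite c(min, max) observations per site.
#' @param waterfowlDensityMean,waterfowlDensitySd pairs/km2 of the
#'   waterfowl breeding-pair density field.
#' @param nPriorityPolygons conservation priority polygon count.
#' @param nTurbinesExisting,nTurbinesProposed turbine counts by status.
#' @return a \linkS4class{LandscapeParams}.
#' @export
landscapeParams <- function(gridShape = c(256L, 256L),
                            cellSizeM = 100,
                            seed = 1L,
                            classProportions = c(
                              "82" = 0.45,  # cultivated crops
                              "71" = 0.30,  # grassland
                              "81" = 0.08,  # hay/pasture
                              "52" = 0.05,  # shrubland
                              "95" = 0.04,  # herbaceous wetlands
                              "11" = 0.03,  # open water
                              "41" = 0.02,  # forest
                              "21" = 0.02,  # developed, open
                              "22" = 0.01), # developed, low
                            lcPatchScale = 600,
                            nWells = 500L, wellClusterSd = 2000,
                            nHamlets = 12L,
                            wpcRange = c(1L, 7L), wpcCorrLength = 5000,
                            nCraneSites = 8L,
                            craneObsPerSite = c(1L, 4L),
                            waterfowlDensityMean = 60,
                            waterfowlDensitySd = 40,
                            nPriorityPolygons = 5L,
                            nTurbinesExisting = 150L,
                            nTurbinesProposed = 350L) {
  p <- new("LandscapeParams",
           gridShape = as.integer(gridShape), cellSizeM = cellSizeM,
           seed = as.integer(seed), classProportions = classProportions,
           lcPatchScale = lcPatchScale, nWells = as.integer(nWells),
           wellClusterSd = wellClusterSd, nHamlets = as.integer(nHamlets),
           wpcRange = as.integer(wpcRange), wpcCorrLength = wpcCorrLength,
           nCraneSites = as.integer(nCraneSites),
           craneObsPerSite = as.integer(craneObsPerSite),
           waterfowlDensityMean = waterfowlDensityMean,
           waterfowlDensitySd = waterfowlDensitySd,
           nPriorityPolygons = as.integer(nPriorityPolygons),
           nTurbinesExisting = as.integer(nTurbinesExisting),
           nTurbinesProposed = as.integer(nTurbinesProposed))
  validObject(p)
  p
}

setMethod("show", "LandscapeParams", function(object) {
  cat("LandscapeParams: ", object@gridShape[1], " x ", object@gridShape[2],
      " cells @ ", object@cellSizeM, " m, seed ", object@seed, "\n", sep = "")
})

# uniform points inside bounds
uniformPoints <- function(n, b) {
  cbind(stats::runif(n, b["xmin"], b["xmax"]),
        stats::runif(n, b["ymin"], b["ymax"]))
}

# Thomas cluster process: cluster centers uniform, offsets Normal(0, sd);
# out-of-bounds draws are re-sampled from their cluster (clamped as a last
# resort so n is exact)
clusteredPoints <- function(n, sd, b) {
  if (n == 0L) return(matrix(numeric(), 0, 2))
  nClusters <- max(1L, round(n / 25))
  centers <- uniformPoints(nClusters, b)
  assign <- sample.int(nClusters, n, replace = TRUE)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      p <- centers[assign[i], ] + stats::rnorm(2, 0, sd)
      if (p[1] >= b["xmin"] && p[1] <= b["xmax"] &&
          p[2] >= b["ymin"] && p[2] <= b["ymax"]) break
    }
    out[i, ] <- c(min(max(p[1], b["xmin"]), b["xmax"]),
                  min(max(p[2], b["ymin"]), b["ymax"]))
  }
  out
}

# axis-aligned rectangle polygons, clipped to bounds
randomRectangles <- function(n, b, minFrac = 0.05, maxFrac = 0.15) {
  ext <- c(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"])
  lapply(seq_len(n), function(i) {
    w <- stats::runif(1, minFrac, maxFrac) * ext[1]
    h <- stats::runif(1, minFrac, maxFrac) * ext[2]
    cx <- stats::runif(1, b["xmin"], b["xmax"])
    cy <- stats::runif(1, b["ymin"], b["ymax"])
    x1 <- max(cx - w / 2, b["xmin"]); x2 <- min(cx + w / 2, b["xmax"])
    y1 <- max(cy - h / 2, b["ymin"]); y2 <- min(cy + h / 2, b["ymax"])
    cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
  })
}

# a polyline crossing the grid left-to-right (or bottom-to-top) with
# jittered interior vertices
crossingPolyline <- function(b, horizontal = TRUE, nVertices = 6) {
  ext <- c(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"])
  t <- seq(0, 1, length.out = nVertices)
  if (horizontal) {
    y0 <- stats::runif(1, b["ymin"] + 0.1 * ext[2], b["ymax"] - 0.1 * ext[2])
    y <- y0 + c(0, stats::rnorm(nVertices - 2, 0, 0.05 * ext[2]), 0)
    y <- pmin(pmax(y, b["ymin"]), b["ymax"])
    cbind(b["xmin"] + t * ext[1], y)
  } else {
    x0 <- stats::runif(1, b["xmin"] + 0.1 * ext[1], b["xmax"] - 0.1 * ext[1])
    x <- x0 + c(0, stats::rnorm(nVertices - 2, 0, 0.05 * ext[1]), 0)
    x <- pmin(pmax(x, b["xmin"]), b["xmax"])
    cbind(x, b["ymin"] + t * ext[2])
  }
}

#' Generate a dated whooping-crane observation history
#'
#' Builds \code{nSites} well-separated sites and draws an observation
#' pattern for each: about half the sites satisfy the repeated-stopover
#' rule (observations in at least two distinct years, or on three or more
#' distinct days of one year) and half are near-miss negatives (one or two
#' days in a single year). Ground-truth labels ship with the points.
#'
#' @param nSites number of sites (>= 1).
#' @param years nonempty vector of candidate calendar years.
#' @param seed integer seed.
#' @param bounds named vector xmin/xmax/ymin/ymax for site placement.
#' @param jitterM within-site scatter of observation coordinates, meters.
#' @return list with \code{observations} (point \linkS4class{FeatureSet}
#'   with ISO-8601 \code{date} and \code{site_id}) and \code{truth}
#'   (data.frame \code{site_id, x, y, repeated}).
#' @export
generateCraneHistory <- function(nSites, years, seed = 1L,
                                 bounds = c(xmin = 0, xmax = 20000,
                                            ymin = 0, ymax = 20000),
                                 jitterM = 30) {
  if (nSites < 1) stop("parameter error: nSites must be >= 1", call. = FALSE)
  if (!length(years)) stop("parameter error: years must be nonempty",
                           call. = FALSE)
  withSeed(layerSeed(seed, 11L), {
    # sites on a jittered lattice: distinct lattice cells guarantee
    # inter-site separation well above the within-site scatter, so the
    # ground-truth site structure is recoverable by clustering
    k <- ceiling(sqrt(nSites))
    cw <- (bounds["xmax"] - bounds["xmin"]) / k
    ch <- (bounds["ymax"] - bounds["ymin"]) / k
    cells <- sample.int(k * k, nSites)
    sites <- cbind(
      bounds["xmin"] + ((cells - 1L) %% k + 0.5) * cw +
        stats::runif(nSites, -0.15, 0.15) * cw,
      bounds["ymin"] + ((cells - 1L) %/% k + 0.5) * ch +
        stats::runif(nSites, -0.15, 0.15) * ch)
    # observation patterns: two qualifying clauses + near-miss negatives
    patterns <- rep(c("multi_year", "three_days", "two_days", "one_day"),
                    length.out = nSites)
    patterns <- sample(patterns)
    geoms <- list(); dates <- character(); siteIds <- integer()
    repeated <- logical(nSites)
    pick <- function(v) v[sample.int(length(v), 1)]
    for (s in seq_len(nSites)) {
      yr <- pick(years)
      ds <- switch(patterns[s],
        multi_year = {
          y2 <- if (length(years) > 1) pick(setdiff(years, yr)) else yr
          repeated[s] <- length(unique(c(yr, y2))) >= 2
          c(sprintf("%d-%02d-%02d", yr, sample(4:5, 1), sample(1:28, 1)),
            sprintf("%d-%02d-%02d", y2, sample(4:5, 1), sample(1:28, 1)))
        },
        three_days = {
          repeated[s] <- TRUE
          days <- sample(1:28, 3)
          sprintf("%d-04-%02d", yr, days)
        },
        two_days = {
          repeated[s] <- FALSE
          sprintf("%d-04-%02d", yr, sample(1:28, 2))
        },
        one_day = {
          repeated[s] <- FALSE
          sprintf("%d-04-%02d", yr, sample(1:28, 1))
        })
      # a one-year two-day site can still qualify if years differ (handled
      # above); re-check the label from the dates themselves
      prs <- as.Date(ds)
      yv <- as.integer(format(prs, "%Y"))
      repeated[s] <- length(unique(yv)) >= 2 ||
        any(tapply(prs, yv, function(d) length(unique(d))) >= 3)
      for (d in ds) {
        p <- sites[s, ] + stats::rnorm(2, 0, jitterM)
        p[1] <- min(max(p[1], bounds["xmin"]), bounds["xmax"])
        p[2] <- min(max(p[2], bounds["ymin"]), bounds["ymax"])
        geoms[[length(geoms) + 1L]] <- matrix(p, 1, 2)
        dates <- c(dates, d)
        siteIds <- c(siteIds, s)
      }
    }
    list(
      observations = featureSet("point", geoms,
                                data.frame(date = dates, site_id = siteIds)),
      truth = data.frame(site_id = seq_len(nSites),
                         x = sites[, 1], y = sites[, 2],
                         repeated = repeated))
  })
}

#' Generate a synthetic study landscape
#'
#' Builds every input layer the siting analysis consumes, on one shared
#' 100 m-class equal-area grid: a patchy categorical land-cover field
#' (quantile-thresholded smoothed noise matching the target class
#' fractions), impervious fraction tied to developed cells, localized
#' topographic-change anomalies standing in for surface mines, a smooth
#' wind power class field, a waterfowl breeding-pair density surface,
#' clustered oil/gas wells, hamlets, roads and named rivers, dated crane
#' observations with ground-truth stopover labels, conservation priority /
#' protected / sensitivity / urban-core polygons, turbines (existing and
#' proposed) and a per-region development-goal table. Deterministic for a
#' fixed seed; layers draw from independent substreams so one layer's
#' parameters do not perturb another's realization.
#'
#' @param params a \linkS4class{LandscapeParams}.
#' @return a \linkS4class{SyntheticLandscape}.
#' @examples
#' ls <- generateLandscape(landscapeParams(gridShape = c(48, 48), seed = 7))
#' gridDims(ls@landcover)
#' @export
generateLandscape <- function(params) {
  validObject(params)
  nr <- params@gridShape[1]; nc <- params@gridShape[2]
  cs <- params@cellSizeM
  seed <- params@seed
  template <- rasterGrid(matrix(0, nr, nc), cellSize = cs)
  b <- gridBounds(template)

  # --- land cover: quantile-thresholded smoothed field -------------------
  lcCodes <- as.integer(names(params@classProportions))
  props <- as.numeric(params@classProportions)
  lc <- withSeed(layerSeed(seed, 1L), {
    f <- gaussianField(nr, nc, params@lcPatchScale / cs)
    qs <- stats::quantile(f, probs = cumsum(props)[-length(props)],
                          names = FALSE)
    matrix(lcCodes[findInterval(f, qs) + 1L], nr, nc)
  })
  landcover <- rasterGrid(lc, cellSize = cs, nodata = 255)

  # --- impervious fraction: nonzero only on developed cells --------------
  developed <- lc %in% c(21L, 22L, 23L, 24L)
  impervious <- withSeed(layerSeed(seed, 2L), {
    v <- matrix(0, nr, nc)
    v[developed] <- stats::runif(sum(developed), 0.2, 0.9)
    rasterGrid(v, cellSize = cs)
  })

  # --- topographic change: a few mine-like anomalies ---------------------
  topo <- withSeed(layerSeed(seed, 3L), {
    v <- matrix(0, nr, nc)
    cc <- cellCenters(template)
    for (i in 1:3) {
      ctr <- uniformPoints(1, b)
      r <- stats::runif(1, 2, 5) * cs
      mag <- stats::runif(1, 12, 25)
      d2 <- (cc$x - ctr[1])^2 + (cc$y - ctr[2])^2
      v <- pmax(v, mag * exp(-d2 / (2 * (r / 2)^2)) * (d2 <= r^2))
    }
    rasterGrid(v, cellSize = cs)
  })

  # --- wind power class: discretized smooth field ------------------------
  wpc <- withSeed(layerSeed(seed, 4L), {
    f <- gaussianField(nr, nc, params@wpcCorrLength / cs)
    k <- params@wpcRange[2] - params@wpcRange[1] + 1L
    if (k == 1L) {
      cls <- matrix(params@wpcRange[1], nr, nc)
    } else {
      qs <- stats::quantile(f, probs = seq_len(k - 1L) / k, names = FALSE)
      cls <- matrix(params@wpcRange[1] + findInterval(f, qs), nr, nc)
    }
    rasterGrid(cls, cellSize = cs, nodata = 255)
  })

  # --- waterfowl pair density --------------------------------------------
  waterfowl <- withSeed(layerSeed(seed, 5L), {
    f <- gaussianField(nr, nc, 2000 / cs)
    v <- params@waterfowlDensityMean + params@waterfowlDensitySd * f
    v[v < 0] <- 0
    rasterGrid(v, cellSize = cs)
  })

  # --- regions: west / east split ----------------------------------------
  regions <- rasterGrid(
    matrix(rep(c(1, 2), times = c(floor(nc / 2), ceiling(nc / 2))),
           nr, nc, byrow = TRUE),
    cellSize = cs, nodata = 255)
  regionNames <- c("west", "east")

  # --- point and line layers ---------------------------------------------
  wells <- withSeed(layerSeed(seed, 6L),
    pointSet(clusteredPoints(params@nWells, params@wellClusterSd, b)))
  hamlets <- withSeed(layerSeed(seed, 7L),
    pointSet(uniformPoints(params@nHamlets, b)))
  roads <- withSeed(layerSeed(seed, 8L),
    featureSet("line", lapply(1:4, function(i)
      crossingPolyline(b, horizontal = i %% 2 == 0))))
  rivers <- withSeed(layerSeed(seed, 9L),
    featureSet("line",
               list(crossingPolyline(b, horizontal = TRUE),
                    crossingPolyline(b, horizontal = FALSE)),
               data.frame(name = c("Missouri", "Little Muddy"))))

  # --- crane observations -------------------------------------------------
  if (params@nCraneSites > 0L) {
    ch <- generateCraneHistory(params@nCraneSites, years = 2008:2012,
                               seed = seed, bounds = b)
    craneObs <- ch$observations
    craneTruth <- ch$truth
  } else {
    craneObs <- featureSet("point")
    craneTruth <- data.frame(site_id = integer(), x = numeric(),
                             y = numeric(), repeated = logical())
  }

  # --- polygon layers ------------------------------------------------------
  priority <- withSeed(layerSeed(seed, 12L), {
    g <- randomRectangles(params@nPriorityPolygons, b)
    featureSet("polygon", g,
               data.frame(name = paste0("priority_", seq_along(g))))
  })
  protected <- withSeed(layerSeed(seed, 13L), {
    g <- randomRectangles(3L, b, 0.04, 0.10)
    featureSet("polygon", g, data.frame(gap_code = c(1L, 2L, 3L)))
  })
  sensitivity <- withSeed(layerSeed(seed, 14L), {
    g <- randomRectangles(6L, b, 0.05, 0.12)
    featureSet("polygon", g, data.frame(category = 1:6))
  })
  urbanCores <- withSeed(layerSeed(seed, 15L), {
    xy <- if (nFeatures(hamlets) >= 2) pointCoords(hamlets)[1:2, , drop = FALSE]
          else matrix(numeric(), 0, 2)
    g <- lapply(seq_len(nrow(xy)), function(i) {
      r <- 500
      x1 <- max(xy[i, 1] - r, b["xmin"]); x2 <- min(xy[i, 1] + r, b["xmax"])
      y1 <- max(xy[i, 2] - r, b["ymin"]); y2 <- min(xy[i, 2] + r, b["ymax"])
      cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
    })
    featureSet("polygon", g)
  })

  # --- turbines -------------------------------------------------------------
  turbines <- withSeed(layerSeed(seed, 16L), {
    n <- params@nTurbinesExisting + params@nTurbinesProposed
    xy <- uniformPoints(n, b)
    idx <- pointToCell(template, xy[, 1], xy[, 2])
    reg <- regionNames[regions@values[cbind(idx$row, idx$col)]]
    pointSet(xy, data.frame(
      status = rep(c("existing", "proposed"),
                   c(params@nTurbinesExisting, params@nTurbinesProposed)),
      region = reg))
  })

  # --- development goals: ~30 GW over ~1.5M km2, scaled to window area ----
  areaKm2 <- (nr * cs / 1000) * (nc * cs / 1000)
  goalPerRegion <- round(30 * (areaKm2 / 2) / 1.5e6, 4)
  goals <- data.frame(region = regionNames,
                      goal_gw = rep(max(goalPerRegion, 1e-4), 2))

  truthDisturbed <- binaryMask(
    matrix(as.double(lc %in% disturbedLandcoverCodes()), nr, nc),
    template, provenance = "generator_truth")

  new("SyntheticLandscape",
      landcover = landcover, impervious = impervious, topoChange = topo,
      wpc = wpc, waterfowlDensity = waterfowl, regions = regions,
      regionNames = regionNames,
      wells = wells, hamlets = hamlets, craneObs = craneObs,
      turbines = turbines, roads = roads, rivers = rivers,
      priorityPolygons = priority, protectedAreas = protected,
      sensitivityZones = sensitivity, urbanCores = urbanCores,
      goals = goals, craneSiteTruth = craneTruth,
      truthDisturbedLc = truthDisturbed, params = params)
}

setMethod("show", "SyntheticLandscape", function(object) {
  d <- gridDims(object@landcover)
  cat("SyntheticLandscape: ", d[1], " x ", d[2], " cells @ ",
      cellSize(object@landcover), " m, seed ", object@params@seed,
      "\n", sep = "")
  cat("  wells: ", nFeatures(object@wells),
      ", hamlets: ", nFeatures(object@hamlets),
      ", crane obs: ", nFeatures(object@craneObs),
      ", turbines: ", nFeatures(object@turbines), "\n", sep = "")
})

#' Rule-resolvable layer map of a synthetic landscape
#'
#' Named list of layers keyed the way the shipped rule sets reference
#' them. The Dakotas rule set (\code{nd_sd}) resolves completely against a
#' generated landscape; conservation-priority style polygon layers are
#' aliased so the Canadian and Montana sets can be exercised too.
#'
#' @param landscape a \linkS4class{SyntheticLandscape}.
#' @return named list of \linkS4class{RasterGrid} /
#'   \linkS4class{FeatureSet} layers.
#' @export
landscapeLayers <- function(landscape) {
  list(
    landcover = landscape@landcover,
    impervious = landscape@impervious,
    topo_change = landscape@topoChange,
    wpc = landscape@wpc,
    waterfowl_density = landscape@waterfowlDensity,
    wells = landscape@wells,
    hamlets = landscape@hamlets,
    crane_obs = landscape@craneObs,
    turbines = landscape@turbines,
    roads = landscape@roads,
    rivers = landscape@rivers,
    tnc_priority = landscape@priorityPolygons,
    iba = landscape@priorityPolygons,
    ncc_priority = landscape@priorityPolygons,
    protected_areas = landscape@protectedAreas,
    sensitivity = landscape@sensitivityZones,
    urban_cores = landscape@urbanCores)
}
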