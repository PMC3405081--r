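#' @include grid.R features.R
NULL

#' Land-cover schema used by the analysis
#'
#' NLCD-style integer codes with labels. The default disturbed set covers
#' cultivated crops, all four developed intensities and hay/pasture; the
#' water set covers open water and wetlands.
#'
#' @return data.frame with columns \code{code}, \code{label}.
#' @export
landcoverSchema <- function() {
  data.frame(
    code = c(11L, 21L, 22L, 23L, 24L, 31L, 41L, 52L, 71L, 81L, 82L, 90L, 95L),
    label = c("open_water", "developed_open", "developed_low",
              "developed_medium", "developed_high", "barren", "forest",
              "shrubland", "grassland", "hay_pasture", "cultivated_crops",
              "woody_wetlands", "herbaceous_wetlands"))
}

#' Default disturbed land-cover codes
#' @export
disturbedLandcoverCodes <- function() c(82L, 24L, 22L, 23L, 21L, 81L)

#' Default water / wetland land-cover codes
#' @export
waterLandcoverCodes <- function() c(11L, 90L, 95L)

#' Disturbance-footprint configuration
#'
#' @param disturbedLcCodes land-cover codes mapped to disturbed.
#' @param imperviousThreshold impervious fraction above which a cell is
#'   disturbed (strict \code{>}; default 0, i.e. any mapped imperviousness).
#' @param topoThresholdByLc named numeric, land-cover code -> meters of
#'   absolute topographic change flagging surface mines and similar. The
#'   source product uses per-cover thresholds between 10.21 and 17.57 m;
#'   values outside that band are rejected unless \code{strictTopo = FALSE}.
#' @param kdeBandwidth quartic-kernel bandwidth (= support radius) for the
#'   well-field density, meters.
#' @param kdeThreshold well density (wells/km2) at or above which a cell is
#'   part of an oil/gas field.
#' @param linearResolution rasterization resolution for linear
#'   infrastructure, meters (default 30).
#' @param hamletBuffer settlement buffer radius, meters (default 300).
#' @param strictTopo enforce the 10.21-17.57 m band on topo thresholds.
#' @return validated configuration list of class \code{DisturbanceConfig}.
#' @export
disturbanceConfig <- function(disturbedLcCodes = disturbedLandcoverCodes(),
                              imperviousThreshold = 0,
                              topoThresholdByLc = NULL,
                              kdeBandwidth = 1000,
                              kdeThreshold = 1,
                              linearResolution = 30,
                              hamletBuffer = 300,
                              strictTopo = TRUE) {
  if (is.null(topoThresholdByLc)) {
    codes <- landcoverSchema()$code
    topoThresholdByLc <- stats::setNames(rep(10.21, length(codes)),
                                         as.character(codes))
  }
  if (imperviousThreshold < 0 || kdeThreshold < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  if (kdeBandwidth <= 0 || linearResolution <= 0)
    stop("bandwidth and resolution must be > 0", call. = FALSE)
  if (hamletBuffer < 0) stop("hamletBuffer must be >= 0", call. = FALSE)
  if (strictTopo && any(topoThresholdByLc < 10.21 | topoThresholdByLc > 17.57))
    stop("topo-change thresholds must lie in [10.21, 17.57] m ",
         "(set strictTopo = FALSE to override)", call. = FALSE)
  structure(list(disturbedLcCodes = as.integer(disturbedLcCodes),
                 imperviousThreshold = imperviousThreshold,
                 topoThresholdByLc = topoThresholdByLc,
                 kdeBandwidth = kdeBandwidth, kdeThreshold = kdeThreshold,
                 linearResolution = linearResolution,
                 hamletBuffer = hamletBuffer),
            class = "DisturbanceConfig")
}

#' Disturbed land-cover mask
#'
#' Marks each cell 1 if its land-cover code is in the disturbed set.
#' Nodata cells propagate as nodata.
#'
#' @param landcover categorical \linkS4class{RasterGrid}.
#' @param codes integer codes considered disturbed; must belong to
#'   \code{schema}.
#' @param schema land-cover schema data.frame (default
#'   \code{\link{landcoverSchema}}).
#' @return a \linkS4class{BinaryMask}.
#' @export
landcoverMask <- function(landcover, codes, schema = landcoverSchema()) {
  codes <- as.integer(codes)
  bad <- setdiff(codes, schema$code)
  if (length(bad))
    stop("configuration error: land-cover code(s) not in schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  v <- landcover@values
  m <- matrix(as.double(v %in% codes), nrow(v), ncol(v))
  m[is.na(v)] <- NA_real_
  binaryMask(m, landcover, provenance = "landcover")
}

#' Impervious-surface mask
#'
#' @param impervious impervious fraction \linkS4class{RasterGrid} (0-1).
#' @param threshold strict lower bound on the fraction (default 0: any
#'   mapped imperviousness counts).
#' @return a \linkS4class{BinaryMask}.
#' @export
imperviousMask <- function(impervious, threshold = 0) {
  v <- impervious@values
  m <- matrix(as.double(v > threshold), nrow(v), ncol(v))
  m[is.na(v)] <- NA_real_
  binaryMask(m, impervious, provenance = "impervious")
}

#' Topographic-change mask
#'
#' Flags cells whose absolute topographic change meets or exceeds the
#' threshold for the cell's land-cover code (per-cover thresholds capture
#' that e.g. forest canopy change is noisier than cropland).
#'
#' @param topoChange \linkS4class{RasterGrid} of change magnitudes (meters).
#' @param landcover aligned categorical \linkS4class{RasterGrid}.
#' @param thresholdByLc named numeric, land-cover code -> meters.
#' @return a \linkS4class{BinaryMask}.
#' @export
topoChangeMask <- function(topoChange, landcover, thresholdByLc) {
  stopIfMisaligned(topoChange, landcover)
  v <- topoChange@values
  lc <- landcover@values
  seen <- unique(lc[!is.na(lc)])
  missing <- setdiff(as.character(seen), names(thresholdByLc))
  if (length(missing))
    stop("configuration error: no topo-change threshold for land-cover ",
         "code(s): ", paste(missing, collapse = ", "), call. = FALSE)
  thr <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(lc)
  thr[ok] <- thresholdByLc[as.character(lc[ok])]
  m <- matrix(as.double(abs(v) >= thr), nrow(v), ncol(v))
  m[is.na(v) | is.na(thr)] <- NA_real_
  binaryMask(m, topoChange, provenance = "topo_change")
}

#' Well-field kernel density
#'
#' Quartic (biweight) kernel density of well points on the cell centers of
#' the template grid, in wells per km2. The kernel has finite support equal
#' to the bandwidth, so the density at a cell is an exact finite sum over
#' nearby wells; the surface integrates to the number of wells over the
#' plane (mass falling off-grid is lost at the boundary).
#'
#' @param wells point \linkS4class{FeatureSet}.
#' @param template \linkS4class{RasterGrid} defining the evaluation grid.
#' @param bandwidth kernel support radius, meters.
#' @return a \linkS4class{RasterGrid} of densities (wells/km2).
#' @export
wellDensity <- function(wells, template, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  d <- dim(template@values)
  dens <- matrix(0, d[1], d[2])
  xy <- if (nFeatures(wells)) pointCoords(wells) else matrix(numeric(), 0, 2)
  if (nrow(xy)) {
    cs <- template@cellSize
    b <- gridBounds(template)
    h2 <- bandwidth^2
    norm <- 3 / (pi * h2)                       # integrates to 1 per well
    xs <- template@xmin + (seq_len(d[2]) - 0.5) * cs
    ys <- b["ymax"] - (seq_len(d[1]) - 0.5) * cs
    for (k in seq_len(nrow(xy))) {
      jr <- which(abs(xs - xy[k, 1]) <= bandwidth)
      ir <- which(abs(ys - xy[k, 2]) <= bandwidth)
      if (!length(jr) || !length(ir)) next
      dx2 <- (xs[jr] - xy[k, 1])^2
      dy2 <- (ys[ir] - xy[k, 2])^2
      d2 <- outer(dy2, dx2, `+`)
      w <- 1 - d2 / h2
      w[w < 0] <- 0
      dens[ir, jr] <- dens[ir, jr] + norm * w^2
    }
  }
  rasterGrid(dens * 1e6,                        # per m2 -> per km2
             xmin = template@xmin, ymin = template@ymin,
             cellSize = template@cellSize, crs = template@crs)
}

#' Well-field (oil and gas field) mask
#'
#' Thresholds the quartic kernel density of well locations: cells at or
#' above \code{threshold} wells/km2 are disturbed oil/gas field.
#'
#' @inheritParams wellDensity
#' @param threshold wells per km2 (inclusive lower bound).
#' @return a \linkS4class{BinaryMask}.
#' @export
wellFieldMask <- function(wells, template, bandwidth, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  dens <- wellDensity(wells, template, bandwidth)
  binaryMask(dens@values >= threshold & nFeatures(wells) > 0, template,
             provenance = "well_field")
}

# Supercover traversal: sub-grid cells crossed by one segment, in a grid of
# `res`-sized cells anchored at (xmin, ymax) with rows increasing southward.
segmentCells <- function(x1, y1, x2, y2, xmin, ymax, res, nrowSub, ncolSub) {
  u1 <- (x1 - xmin) / res; u2 <- (x2 - xmin) / res
  v1 <- (ymax - y1) / res; v2 <- (ymax - y2) / res
  ts <- c(0, 1)
  if (u1 != u2) {
    k <- seq(ceiling(min(u1, u2)), floor(max(u1, u2)))
    ts <- c(ts, (k - u1) / (u2 - u1))
  }
  if (v1 != v2) {
    k <- seq(ceiling(min(v1, v2)), floor(max(v1, v2)))
    ts <- c(ts, (k - v1) / (v2 - v1))
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  tm <- c(tm, 0, 1)                             # midpoints + endpoints
  cu <- floor(u1 + tm * (u2 - u1)) + 1L
  cv <- floor(v1 + tm * (v2 - v1)) + 1L
  ok <- cu >= 1L & cu <= ncolSub & cv >= 1L & cv <= nrowSub
  unique(cbind(row = cv[ok], col = cu[ok]))
}

#' Linear-infrastructure mask
#'
#' Rasterizes line features (roads, pipelines, railways, transmission
#' lines) at a fine resolution and aggregates to the analysis grid: an
#' analysis cell is 1 if any sub-cell it contains is crossed by a line.
#'
#' @param lines line \linkS4class{FeatureSet}.
#' @param template analysis \linkS4class{RasterGrid}.
#' @param resolution rasterization resolution, meters (default 30).
#' @return a \linkS4class{BinaryMask}.
#' @export
linearMask <- function(lines, template, resolution = 30) {
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  d <- dim(template@values)
  b <- gridBounds(template)
  nrowSub <- ceiling((b["ymax"] - b["ymin"]) / resolution)
  ncolSub <- ceiling((b["xmax"] - b["xmin"]) / resolution)
  hit <- matrix(FALSE, d[1], d[2])
  for (g in featureCoords(lines)) {
    for (i in seq_len(nrow(g) - 1L)) {
      sc <- segmentCells(g[i, 1], g[i, 2], g[i + 1L, 1], g[i + 1L, 2],
                         b["xmin"], b["ymax"], resolution, nrowSub, ncolSub)
      if (!nrow(sc)) next
      # sub-cell centers -> analysis cells
      px <- b["xmin"] + (sc[, "col"] - 0.5) * resolution
      py <- b["ymax"] - (sc[, "row"] - 0.5) * resolution
      idx <- pointToCell(template, px, py)
      ok <- !is.na(idx$row)
      hit[cbind(idx$row[ok], idx$col[ok])] <- TRUE
    }
  }
  binaryMask(hit, template, provenance = "linear_infrastructure")
}

#' Buffered-point mask
#'
#' Marks every cell whose center lies within \code{radius} of any point
#' (e.g. the 300 m settlement buffer around hamlets).
#'
#' @param points point \linkS4class{FeatureSet}.
#' @param template analysis \linkS4class{RasterGrid}.
#' @param radius buffer radius, meters.
#' @return a \linkS4class{BinaryMask}.
#' @export
pointBufferMask <- function(points, template, radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  d <- dim(template@values)
  hit <- matrix(FALSE, d[1], d[2])
  xy <- if (nFeatures(points)) pointCoords(points) else matrix(numeric(), 0, 2)
  if (nrow(xy)) {
    cs <- template@cellSize
    b <- gridBounds(template)
    xs <- template@xmin + (seq_len(d[2]) - 0.5) * cs
    ys <- b["ymax"] - (seq_len(d[1]) - 0.5) * cs
    r2 <- radius^2
    for (k in seq_len(nrow(xy))) {
      jr <- which(abs(xs - xy[k, 1]) <= radius)
      ir <- which(abs(ys - xy[k, 2]) <= radius)
      if (!length(jr) || !length(ir)) next
      d2 <- outer((ys[ir] - xy[k, 2])^2, (xs[jr] - xy[k, 1])^2, `+`)
      hit[ir, jr] <- hit[ir, jr] | d2 <= r2
    }
  }
  binaryMask(hit, template, provenance = "point_buffer")
}

#' Union of binary masks
#'
#' Cellwise logical OR; a cell is nodata only where every input is nodata
#' (a missing source contributes 0, not missingness). Provenance lists are
#' concatenated.
#'
#' @param masks list of aligned \linkS4class{BinaryMask} objects.
#' @return a \linkS4class{BinaryMask}.
#' @export
unionMasks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  do.call(stopIfMisaligned, c(masks, list(what = "masks")))
  acc <- matrix(0, nrow(masks[[1]]@values), ncol(masks[[1]]@values))
  allNA <- matrix(TRUE, nrow(acc), ncol(acc))
  prov <- character()
  for (m in masks) {
    v <- m@values
    isna <- is.na(v)
    v[isna] <- 0
    acc <- pmax(acc, v)
    allNA <- allNA & isna
    prov <- c(prov, m@provenance)
  }
  acc[allNA] <- NA_real_
  binaryMask(acc, masks[[1]], provenance = prov)
}

#' Full disturbance footprint
#'
#' Composes the binary disturbed/undisturbed classification: disturbed
#' land-cover classes, impervious surface, significant topographic change,
#' well-field kernel density, rasterized linear infrastructure, and
#' buffered settlements — a cell with any of these impacts is disturbed.
#'
#' @param landcover,impervious,topoChange aligned \linkS4class{RasterGrid}s
#'   (\code{impervious} and \code{topoChange} may be NULL to skip).
#' @param wells,hamlets point \linkS4class{FeatureSet}s (NULL to skip).
#' @param lines line \linkS4class{FeatureSet} (NULL to skip).
#' @param config a \code{\link{disturbanceConfig}}.
#' @return a \linkS4class{BinaryMask} with full provenance.
#' @export
disturbanceMask <- function(landcover, impervious = NULL, topoChange = NULL,
                            wells = NULL, lines = NULL, hamlets = NULL,
                            config = disturbanceConfig()) {
  masks <- list(landcoverMask(landcover, config$disturbedLcCodes))
  if (!is.null(impervious))
    masks <- c(masks, imperviousMask(impervious, config$imperviousThreshold))
  if (!is.null(topoChange))
    masks <- c(masks, topoChangeMask(topoChange, landcover,
                                     config$topoThresholdByLc))
  if (!is.null(wells))
    masks <- c(masks, wellFieldMask(wells, landcover, config$kdeBandwidth,
                                    config$kdeThreshold))
  if (!is.null(lines))
    masks <- c(masks, linearMask(lines, landcover, config$linearResolution))
  if (!is.null(hamlets))
    masks <- c(masks, pointBufferMask(hamlets, landcover,
                                      config$hamletBuffer))
  unionMasks(masks)
}
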