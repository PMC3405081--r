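#' @include suitability.R
NULL

# shift a matrix by (dr, dc), filling exposed cells with `fill`
shiftMat <- function(m, dr, dc, fill = Inf) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
  cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighborShifts <- function(connectivity) {
  s4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 4) s4
  else c(s4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
}

#' Label connected patches of a binary mask
#'
#' Maximal connected components of the foreground (value 1) under 4- or
#' 8-connectivity, by iterative minimum-label propagation. Background and
#' nodata cells get label 0; patch ids are contiguous from 1.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return list with \code{labels} (a \linkS4class{RasterGrid} of integer
#'   patch ids) and \code{table} (data.frame \code{patch_id, cell_count,
#'   area_km2}).
#' @export
labelPatches <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- mask@values
  fg <- !is.na(v) & v == 1
  d <- dim(fg)
  L <- matrix(Inf, d[1], d[2])
  L[fg] <- seq_len(sum(fg))
  shifts <- neighborShifts(connectivity)
  repeat {
    M <- L
    for (s in shifts) M <- pmin(M, shiftMat(L, s[1], s[2]))
    M[!fg] <- Inf
    if (identical(M, L)) break
    L <- M
  }
  lab <- matrix(0, d[1], d[2])
  if (any(fg)) {
    ids <- sort(unique(L[fg]))
    lab[fg] <- match(L[fg], ids)
  }
  cnt <- if (any(fg)) as.integer(table(lab[lab > 0])) else integer()
  tab <- data.frame(patch_id = seq_along(cnt), cell_count = cnt,
                    area_km2 = cnt * cellAreaKm2(mask))
  list(labels = rasterGrid(lab, xmin = mask@xmin, ymin = mask@ymin,
                           cellSize = mask@cellSize, crs = mask@crs,
                           nodata = 0),
       table = tab)
}

#' Remove small, isolated patches
#'
#' Retains every patch with area at least \code{minAreaKm2}; retains a
#' smaller patch only if its minimum cell-center distance to any patch of
#' at least \code{minAreaKm2} is at most \code{maxDistance}. All other
#' patches are removed. This drops disturbed fragments too small and too
#' far from developable patches to support wind infrastructure.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param minAreaKm2 area threshold, km2 (default 1).
#' @param maxDistance isolation threshold, meters (default 800).
#' @param connectivity 4 or 8 (default 8).
#' @return filtered \linkS4class{BinaryMask} (subset of the input).
#' @export
filterSmallIsolated <- function(mask, minAreaKm2 = 1, maxDistance = 800,
                                connectivity = 8) {
  stopifnot(minAreaKm2 > 0, maxDistance >= 0)
  lp <- labelPatches(mask, connectivity)
  tab <- lp$table
  if (!nrow(tab)) return(mask)
  lab <- lp$labels@values
  large <- tab$patch_id[tab$area_km2 >= minAreaKm2]
  small <- tab$patch_id[tab$area_km2 < minAreaKm2]
  keep <- large
  if (length(small) && length(large)) {
    cc <- cellCenters(mask)
    inLarge <- lab %in% large
    A <- cbind(cc$x[inLarge], cc$y[inLarge])
    for (p in small) {
      inP <- lab == p
      P <- cbind(cc$x[inP], cc$y[inP])
      dmin <- Inf
      for (i in seq_len(nrow(P))) {
        dmin <- min(dmin, min((A[, 1] - P[i, 1])^2 + (A[, 2] - P[i, 2])^2))
        if (sqrt(dmin) <= maxDistance) break
      }
      if (sqrt(dmin) <= maxDistance) keep <- c(keep, p)
    }
  }
  v <- mask@values
  out <- matrix(as.double(lab %in% keep), nrow(v), ncol(v))
  out[is.na(v)] <- NA_real_
  binaryMask(out, mask, provenance = c(mask@provenance, "patch_filter"))
}
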