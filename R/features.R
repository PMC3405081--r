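#' @include AllClasses.R
NULL

#' @describeIn featureSet geometry type of the collection.
#' @param x a FeatureSet.
#' @export
setMethod("geomType", "FeatureSet", function(x) x@geomType)

#' @describeIn featureSet list of coordinate matrices.
#' @export
setMethod("featureCoords", "FeatureSet", function(x) x@geoms)

#' @describeIn featureSet attribute data.frame.
#' @export
setMethod("featureAttrs", "FeatureSet", function(x) x@attrs)

#' @describeIn featureSet number of features.
#' @export
setMethod("nFeatures", "FeatureSet", function(x) length(x@geoms))

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet: ", length(object@geoms), " ", object@geomType,
      " feature(s) [", object@crs, "]\n", sep = "")
  if (ncol(object@attrs))
    cat("  attributes:", paste(names(object@attrs), collapse = ", "), "\n")
})

#' All point coordinates of a point FeatureSet as a matrix
#' @param fs a point \linkS4class{FeatureSet}.
#' @return n-by-2 numeric matrix.
#' @export
pointCoords <- function(fs) {
  stopifnot(fs@geomType == "point")
  if (!length(fs@geoms)) return(matrix(numeric(), 0, 2))
  do.call(rbind, fs@geoms)
}

#' Subset a FeatureSet by feature index
#' @param fs a \linkS4class{FeatureSet}.
#' @param i integer or logical index.
#' @export
subsetFeatures <- function(fs, i) {
  idx <- seq_along(fs@geoms)[i]
  featureSet(fs@geomType, fs@geoms[idx],
             fs@attrs[idx, , drop = FALSE], fs@crs)
}

# --- geometry primitives ---------------------------------------------------

# Even-odd (ray casting) point-in-polygon test. ring: unclosed n-by-2
# matrix; px, py vectors. Boundary points count as inside on the lower/left
# crossing side; exact-boundary behavior is not relied upon by callers.
pointsInRing <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from each point (px, py) to a polyline (n-by-2 vertices).
distToPolyline <- function(px, py, line) {
  dmin <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1L)) {
    x1 <- line[i, 1]; y1 <- line[i, 2]
    x2 <- line[i + 1L, 1]; y2 <- line[i + 1L, 2]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      d <- sqrt((px - x1)^2 + (py - y1)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
      d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}
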