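#' @include AllClasses.R
NULL

#' @describeIn rasterGrid cell value matrix (row 1 = north).
#' @param x a RasterGrid.
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @export
setReplaceMethod("gridValues", "RasterGrid", function(x, value) {
  storage.mode(value) <- "double"
  x@values <- value
  validObject(x)
  x
})

#' @describeIn rasterGrid cell side length in meters.
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @describeIn rasterGrid c(rows, cols).
#' @export
setMethod("gridDims", "RasterGrid", function(x) dim(x@values))

#' @describeIn rasterGrid named vector xmin/xmax/ymin/ymax (meters).
#' @export
setMethod("gridBounds", "RasterGrid", function(x) {
  d <- dim(x@values)
  c(xmin = x@xmin, xmax = x@xmin + d[2] * x@cellSize,
    ymin = x@ymin, ymax = x@ymin + d[1] * x@cellSize)
})

#' @describeIn rasterGrid CRS label.
#' @export
setMethod("crsName", "RasterGrid", function(x) x@crs)

#' @describeIn rasterGrid on-disk nodata sentinel.
#' @export
setMethod("nodataValue", "RasterGrid", function(x) x@nodata)

#' @export
setMethod("provenance", "BinaryMask", function(x) x@provenance)

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  cat(class(object), ": ", d[1], " x ", d[2], " cells @ ",
      object@cellSize, " m [", object@crs, "]\n", sep = "")
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat("  values: [", format(min(v)), ", ", format(max(v)), "], ",
        sum(is.na(object@values)), " NA\n", sep = "")
  if (is(object, "BinaryMask") && length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = ", "), "\n")
})

#' Cell-center coordinates of a grid
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @return list with matrices \code{x} and \code{y} of cell-center
#'   coordinates, shaped like the value matrix.
#' @export
cellCenters <- function(grid) {
  d <- dim(grid@values)
  cs <- grid@cellSize
  ymax <- grid@ymin + d[1] * cs
  xs <- grid@xmin + (seq_len(d[2]) - 0.5) * cs
  ys <- ymax - (seq_len(d[1]) - 0.5) * cs
  list(x = matrix(xs, d[1], d[2], byrow = TRUE),
       y = matrix(ys, d[1], d[2]))
}

#' Cell area in km2
#' @param grid a \linkS4class{RasterGrid}.
#' @export
cellAreaKm2 <- function(grid) (grid@cellSize / 1000)^2

#' Do two grids share shape and georeferencing?
#' @param a,b RasterGrids.
#' @export
sameGeoref <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(c(a@xmin, a@ymin, a@cellSize),
                     c(b@xmin, b@ymin, b@cellSize))) &&
    a@crs == b@crs
}

stopIfMisaligned <- function(..., what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!sameGeoref(gs[[1]], gs[[i]]))
      stop("alignment error: ", what, " do not share georeferencing",
           call. = FALSE)
  invisible(TRUE)
}

#' Map point coordinates to grid row/col indices
#'
#' Half-open cell convention: a cell owns its top and left edges, so a point
#' exactly on an interior boundary belongs to the cell below/right of it.
#' Points outside the grid get NA indices.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param x,y numeric vectors of projected coordinates (meters).
#' @return list with integer vectors \code{row} and \code{col} (NA outside).
#' @export
pointToCell <- function(grid, x, y) {
  d <- dim(grid@values)
  cs <- grid@cellSize
  ymax <- grid@ymin + d[1] * cs
  col <- floor((x - grid@xmin) / cs) + 1L
  row <- floor((ymax - y) / cs) + 1L
  # the far edges (x = xmax, y = ymin) belong to the last cell
  col[x == grid@xmin + d[2] * cs] <- d[2]
  row[y == grid@ymin] <- d[1]
  out <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Nearest-neighbor regrid onto a template
#'
#' Each template cell takes the source value at its center. Used to align
#' wind-resource grids delivered at a different resolution (e.g. 200 m US
#' pixels, 5 km Canadian pixels) onto the analysis grid.
#'
#' @param source a \linkS4class{RasterGrid} to resample.
#' @param template a \linkS4class{RasterGrid} defining the output geometry.
#' @return a \linkS4class{RasterGrid} shaped like \code{template}.
#' @export
regridNearest <- function(source, template) {
  if (source@crs != template@crs)
    stop("alignment error: CRS mismatch between source and template",
         call. = FALSE)
  cc <- cellCenters(template)
  idx <- pointToCell(source, as.vector(cc$x), as.vector(cc$y))
  d <- dim(template@values)
  out <- matrix(NA_real_, d[1], d[2])
  ok <- !is.na(idx$row)
  out[ok] <- source@values[cbind(idx$row[ok], idx$col[ok])]
  rasterGrid(out, xmin = template@xmin, ymin = template@ymin,
             cellSize = template@cellSize, crs = template@crs,
             nodata = source@nodata)
}
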