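#' @include synth.R
NULL

#' Write a grid as ESRI ASCII raster
#'
#' Plain-text single-band raster (\code{.asc}): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows north to south. The CRS label is written to a \code{.prj} sidecar;
#' values round-trip losslessly at full double precision.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output path (conventionally \code{.asc}).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path) {
  d <- dim(grid@values)
  v <- grid@values
  v[is.na(v)] <- grid@nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", d[2]),
    paste("nrows", d[1]),
    paste("xllcorner", format(grid@xmin, digits = 17)),
    paste("yllcorner", format(grid@ymin, digits = 17)),
    paste("cellsize", format(grid@cellSize, digits = 17)),
    paste("NODATA_value", format(grid@nodata, digits = 17))), con)
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(grid@crs, sub("\\.asc$", ".prj", path, ignore.case = TRUE))
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' Requires the \code{.prj} CRS sidecar written by
#' \code{\link{writeAsciiGrid}}; a raster without a CRS is refused.
#'
#' @param path \code{.asc} file path.
#' @return a \linkS4class{RasterGrid}.
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path))
    stop("I/O error: no such file: ", path, call. = FALSE)
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  if (!file.exists(prj) || prj == path)
    stop("I/O error: raster '", path, "' has no CRS sidecar (.prj)",
         call. = FALSE)
  crs <- readLines(prj, n = 1)
  hdr <- utils::read.table(path, nrows = 6,
                           col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  h <- stats::setNames(hdr$value, tolower(hdr$key))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  if (!identical(dim(v), c(as.integer(h["nrows"]), as.integer(h["ncols"]))))
    stop("I/O error: raster body does not match header dimensions",
         call. = FALSE)
  v[v == h["nodata_value"]] <- NA_real_
  rasterGrid(v, xmin = unname(h["xllcorner"]), ymin = unname(h["yllcorner"]),
             cellSize = unname(h["cellsize"]), crs = crs,
             nodata = unname(h["nodata_value"]))
}

# FeatureSet geometry -> GeoJSON geometry list
geomToGeoJSON <- function(geomType, m) {
  coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  switch(geomType,
    point = list(type = "Point", coordinates = c(m[1, 1], m[1, 2])),
    line = list(type = "LineString", coordinates = coords),
    polygon = list(type = "Polygon",
                   coordinates = list(c(coords, coords[1]))))
}

#' Write a FeatureSet as GeoJSON
#'
#' One FeatureCollection per layer; attributes become feature properties
#' (dates stay ISO-8601 strings). Polygon rings are closed on output.
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param path output \code{.geojson} path.
#' @return \code{path}, invisibly.
#' @export
writeGeoJSON <- function(fs, path) {
  feats <- lapply(seq_len(nFeatures(fs)), function(i) {
    props <- if (ncol(fs@attrs)) as.list(fs@attrs[i, , drop = FALSE])
             else stats::setNames(list(), character())
    list(type = "Feature",
         geometry = geomToGeoJSON(fs@geomType, fs@geoms[[i]]),
         properties = props)
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = fs@crs)),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' Supports Point, LineString and Polygon (outer ring) geometries; the
#' collection must be homogeneous. An empty collection is a valid empty
#' FeatureSet.
#'
#' @param path \code{.geojson} file.
#' @param expect optionally require \code{"point"}, \code{"line"} or
#'   \code{"polygon"}; a mismatch is a data error.
#' @return a \linkS4class{FeatureSet}.
#' @export
readGeoJSON <- function(path, expect = NULL) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("data error: '", path, "' is not a GeoJSON FeatureCollection",
         call. = FALSE)
  crs <- if (!is.null(obj$crs$properties$name)) obj$crs$properties$name
         else "LOCAL_EQUAL_AREA_M"
  feats <- obj$features
  if (!length(feats)) {
    gt <- if (is.null(expect)) "point" else expect
    return(featureSet(gt, crs = crs))
  }
  kinds <- vapply(feats, function(f) f$geometry$type, character(1))
  kind <- unique(kinds)
  if (length(kind) != 1L)
    stop("data error: mixed geometry types in '", path, "'", call. = FALSE)
  gt <- unname(c(Point = "point", LineString = "line",
                 Polygon = "polygon")[kind])
  if (is.na(gt))
    stop("data error: unsupported geometry type '", kind, "'", call. = FALSE)
  if (!is.null(expect) && gt != expect)
    stop("data error: expected ", expect, " layer but '", path,
         "' contains ", gt, " features", call. = FALSE)
  geoms <- lapply(feats, function(f) {
    cc <- f$geometry$coordinates
    m <- switch(gt,
      point = matrix(unlist(cc), 1, 2),
      line = do.call(rbind, lapply(cc, unlist)),
      polygon = {
        ring <- do.call(rbind, lapply(cc[[1]], unlist))
        if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
          ring <- ring[-nrow(ring), , drop = FALSE]
        ring
      })
    m
  })
  props <- lapply(feats, function(f) f$properties)
  hasProps <- any(vapply(props, length, integer(1)) > 0)
  attrs <- if (hasProps) {
    do.call(rbind, lapply(props, function(p)
      as.data.frame(lapply(p, function(x) if (is.null(x)) NA else x),
                    stringsAsFactors = FALSE)))
  } else data.frame()
  featureSet(gt, geoms, attrs, crs)
}

#' Write a synthetic landscape to a directory
#'
#' Grids as ESRI ASCII (+ .prj), vector layers as GeoJSON, development
#' goals and crane ground truth as CSV.
#'
#' @param landscape a \linkS4class{SyntheticLandscape}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeLandscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeAsciiGrid(landscape@landcover, p("landcover.asc"))
  writeAsciiGrid(landscape@impervious, p("impervious.asc"))
  writeAsciiGrid(landscape@topoChange, p("topo_change.asc"))
  writeAsciiGrid(landscape@wpc, p("wpc.asc"))
  writeAsciiGrid(landscape@waterfowlDensity, p("waterfowl_density.asc"))
  writeAsciiGrid(landscape@regions, p("regions.asc"))
  writeGeoJSON(landscape@wells, p("wells.geojson"))
  writeGeoJSON(landscape@hamlets, p("hamlets.geojson"))
  writeGeoJSON(landscape@craneObs, p("crane_obs.geojson"))
  writeGeoJSON(landscape@turbines, p("turbines.geojson"))
  writeGeoJSON(landscape@roads, p("roads.geojson"))
  writeGeoJSON(landscape@rivers, p("rivers.geojson"))
  writeGeoJSON(landscape@priorityPolygons, p("priority_polygons.geojson"))
  writeGeoJSON(landscape@protectedAreas, p("protected_areas.geojson"))
  writeGeoJSON(landscape@sensitivityZones, p("sensitivity_zones.geojson"))
  writeGeoJSON(landscape@urbanCores, p("urban_cores.geojson"))
  utils::write.csv(landscape@goals, p("goals.csv"), row.names = FALSE)
  utils::write.csv(landscape@craneSiteTruth, p("crane_site_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
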