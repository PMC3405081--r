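#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# RasterGrid
# ---------------------------------------------------------------------------

#' RasterGrid: a single-band georeferenced raster
#'
#' A rectangular grid of numeric or categorical cell values with affine
#' georeferencing in a projected, meter-unit, equal-area coordinate system.
#' Row 1 of the value matrix is the northernmost row; missing cells are
#' stored as \code{NA} in memory and as \code{nodata} on disk.
#'
#' @slot values numeric matrix of cell values (row 1 = north).
#' @slot xmin,ymin coordinates of the lower-left grid corner (meters).
#' @slot cellSize side length of the square cells (meters).
#' @slot crs free-text label of the projected CRS; grids only combine when
#'   their labels match.
#' @slot nodata sentinel written for \code{NA} cells on disk.
#'
#' @aliases RasterGrid
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(
    values   = "matrix",
    xmin     = "numeric",
    ymin     = "numeric",
    cellSize = "numeric",
    crs      = "character",
    nodata   = "numeric"
  ),
  prototype(
    xmin = 0, ymin = 0, cellSize = 100,
    crs = "LOCAL_EQUAL_AREA_M", nodata = -9999
  )
)

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    msg <- c(msg, "grid must have at least one row and column")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@xmin) != 1L || length(object@ymin) != 1L)
    msg <- c(msg, "xmin/ymin must be scalars")
  if (length(object@crs) != 1L || !nzchar(object@crs))
    msg <- c(msg, "crs must be a nonempty string")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param xmin,ymin lower-left corner coordinates in meters.
#' @param cellSize cell side length in meters.
#' @param crs CRS label; all grids in an analysis must share it.
#' @param nodata on-disk sentinel for missing cells.
#' @return a \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(1:6, 2, 3), cellSize = 100)
#' gridDims(g)
#' @export
rasterGrid <- function(values, xmin = 0, ymin = 0, cellSize = 100,
                       crs = "LOCAL_EQUAL_AREA_M", nodata = -9999) {
  if (is.logical(values) || is.integer(values)) storage.mode(values) <- "double"
  new("RasterGrid", values = values, xmin = xmin, ymin = ymin,
      cellSize = cellSize, crs = crs, nodata = nodata)
}

# ---------------------------------------------------------------------------
# BinaryMask
# ---------------------------------------------------------------------------

#' BinaryMask: a 0/1 raster with provenance
#'
#' A \linkS4class{RasterGrid} restricted to values 0, 1 and \code{NA},
#' carrying the identifiers of the source rules or layers that produced it.
#'
#' @slot provenance character vector of source-rule identifiers.
#' @aliases BinaryMask
#' @exportClass BinaryMask
setClass("BinaryMask",
  contains = "RasterGrid",
  representation(provenance = "character"),
  prototype(provenance = character())
)

setValidity("BinaryMask", function(object) {
  v <- object@values
  bad <- !(is.na(v) | v == 0 | v == 1)
  if (any(bad)) "mask values must be 0, 1 or NA" else TRUE
})

#' Construct a BinaryMask on a template grid's georeferencing
#'
#' @param values logical or 0/1 numeric matrix.
#' @param template a \linkS4class{RasterGrid} supplying georeferencing.
#' @param provenance character vector of source identifiers.
#' @return a \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(values, template, provenance = character()) {
  if (is.logical(values)) {
    v <- matrix(as.double(values), nrow(values), ncol(values))
    v[is.na(values)] <- NA_real_
  } else {
    v <- values
    storage.mode(v) <- "double"
  }
  new("BinaryMask", values = v, xmin = template@xmin, ymin = template@ymin,
      cellSize = template@cellSize, crs = template@crs, nodata = 255,
      provenance = provenance)
}

# ---------------------------------------------------------------------------
# FeatureSet
# ---------------------------------------------------------------------------

#' FeatureSet: typed vector features with attributes
#'
#' A homogeneous collection of point, line or polygon geometries with an
#' attribute table (one row per feature). Coordinates are projected meters
#' in the same CRS as the analysis grids. Polygons are single outer rings
#' (unclosed; the closing edge is implied).
#'
#' @slot geomType one of \code{"point"}, \code{"line"}, \code{"polygon"}.
#' @slot geoms list of n-by-2 coordinate matrices, one per feature
#'   (points: a single row).
#' @slot attrs data.frame of feature attributes, \code{nrow == length(geoms)}.
#' @slot crs CRS label.
#' @aliases FeatureSet
#' @exportClass FeatureSet
setClass("FeatureSet",
  representation(
    geomType = "character",
    geoms    = "list",
    attrs    = "data.frame",
    crs      = "character"
  ),
  prototype(geomType = "point", geoms = list(),
            attrs = data.frame(), crs = "LOCAL_EQUAL_AREA_M")
)

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!object@geomType %in% c("point", "line", "polygon"))
    msg <- c(msg, "geomType must be point, line or polygon")
  ok <- vapply(object@geoms, function(g)
    is.matrix(g) && ncol(g) == 2L && nrow(g) >= 1L && all(is.finite(g)),
    logical(1))
  if (!all(ok)) msg <- c(msg, "each geometry must be a finite n-by-2 matrix")
  if (object@geomType == "point" &&
      any(vapply(object@geoms, nrow, integer(1)) != 1L))
    msg <- c(msg, "point geometries must have exactly one coordinate row")
  if (object@geomType == "line" &&
      any(vapply(object@geoms, nrow, integer(1)) < 2L))
    msg <- c(msg, "line geometries need at least two vertices")
  if (object@geomType == "polygon" &&
      any(vapply(object@geoms, nrow, integer(1)) < 3L))
    msg <- c(msg, "polygon rings need at least three vertices")
  if (nrow(object@attrs) > 0L && nrow(object@attrs) != length(object@geoms))
    msg <- c(msg, "attrs must have one row per feature")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureSet
#'
#' @param geomType \code{"point"}, \code{"line"} or \code{"polygon"}.
#' @param geoms list of n-by-2 coordinate matrices.
#' @param attrs data.frame of per-feature attributes (optional).
#' @param crs CRS label.
#' @return a \linkS4class{FeatureSet}.
#' @examples
#' pts <- featureSet("point", list(cbind(10, 20), cbind(30, 40)),
#'                   data.frame(name = c("a", "b")))
#' nFeatures(pts)
#' @export
featureSet <- function(geomType, geoms = list(),
                       attrs = data.frame(), crs = "LOCAL_EQUAL_AREA_M") {
  if (nrow(attrs) == 0L && length(geoms) > 0L)
    attrs <- data.frame(row.names = seq_along(geoms))
  new("FeatureSet", geomType = geomType, geoms = geoms,
      attrs = attrs, crs = crs)
}

#' Shorthand for a point FeatureSet from a coordinate matrix
#' @param xy n-by-2 matrix of point coordinates.
#' @param attrs optional attribute data.frame.
#' @param crs CRS label.
#' @export
pointSet <- function(xy, attrs = data.frame(), crs = "LOCAL_EQUAL_AREA_M") {
  xy <- matrix(as.numeric(xy), ncol = 2)
  featureSet("point", lapply(seq_len(nrow(xy)), function(i) xy[i, , drop = FALSE]),
             attrs, crs)
}

# ---------------------------------------------------------------------------
# Exclusion rules
# ---------------------------------------------------------------------------

.RULE_OPERATORS <- c("polygon_burn", "category_at_least", "category_in_set",
                     "density_at_least", "point_buffer", "line_buffer",
                     "repeated_stopover_buffer")

#' ExclusionRule: one declarative wildlife-exclusion rule
#'
#' A rule names a source layer, an operator and operator-specific parameters;
#' compiling it against a layer map yields a \linkS4class{BinaryMask}.
#'
#' @slot ruleId unique identifier within its rule set.
#' @slot source name of the input layer the rule reads.
#' @slot operator one of \code{polygon_burn}, \code{category_at_least},
#'   \code{category_in_set}, \code{density_at_least}, \code{point_buffer},
#'   \code{line_buffer}, \code{repeated_stopover_buffer}.
#' @slot params operator-specific named list (radii in meters, thresholds in
#'   the layer's units, category sets, attribute filters).
#' @aliases ExclusionRule
#' @exportClass ExclusionRule
setClass("ExclusionRule",
  representation(ruleId = "character", source = "character",
                 operator = "character", params = "list"))

setValidity("ExclusionRule", function(object) {
  msg <- character()
  if (!object@operator %in% .RULE_OPERATORS)
    msg <- c(msg, paste0("unknown operator '", object@operator, "'"))
  for (p in c("radius", "buffer_radius", "site_radius"))
    if (!is.null(object@params[[p]]) && object@params[[p]] < 0)
      msg <- c(msg, paste0(p, " must be >= 0"))
  if (object@operator %in% c("density_at_least", "category_at_least") &&
      is.null(object@params$threshold))
    msg <- c(msg, paste0(object@operator, " requires a threshold"))
  if (object@operator == "category_in_set" &&
      is.null(object@params$categories))
    msg <- c(msg, "category_in_set requires categories")
  if (object@operator %in% c("point_buffer", "line_buffer") &&
      is.null(object@params$radius))
    msg <- c(msg, paste0(object@operator, " requires a radius"))
  if (length(msg)) msg else TRUE
})

#' Construct an ExclusionRule
#' @param ruleId unique identifier.
#' @param source input layer name.
#' @param operator rule operator (see \linkS4class{ExclusionRule}).
#' @param ... operator parameters (e.g. \code{radius}, \code{threshold},
#'   \code{categories}, \code{where} for attribute filters).
#' @return an \linkS4class{ExclusionRule}.
#' @export
exclusionRule <- function(ruleId, source, operator, ...) {
  new("ExclusionRule", ruleId = ruleId, source = source,
      operator = operator, params = list(...))
}

#' RuleSet: an ordered, jurisdiction-specific list of exclusion rules
#'
#' @slot jurisdiction jurisdiction label (e.g. \code{"nd_sd"}).
#' @slot rules list of \linkS4class{ExclusionRule}; ruleIds must be unique.
#' @aliases RuleSet
#' @exportClass RuleSet
setClass("RuleSet",
  representation(jurisdiction = "character", rules = "list"))

setValidity("RuleSet", function(object) {
  ok <- vapply(object@rules, is, logical(1), class2 = "ExclusionRule")
  if (!all(ok)) return("rules must all be ExclusionRule objects")
  ids <- vapply(object@rules, function(r) r@ruleId, character(1))
  if (anyDuplicated(ids)) return("rule ids must be unique within a rule set")
  TRUE
})

#' Construct a RuleSet
#' @param jurisdiction jurisdiction label.
#' @param rules list of \linkS4class{ExclusionRule} objects.
#' @return a \linkS4class{RuleSet}.
#' @export
ruleSet <- function(jurisdiction, rules = list()) {
  new("RuleSet", jurisdiction = jurisdiction, rules = rules)
}

# ---------------------------------------------------------------------------
# Capacity density
# ---------------------------------------------------------------------------

#' CapacityDensityTable: installable MW per km2 by wind power class
#'
#' The reference assumption is 5 MW/km2 of nameplate capacity at a 44.5%
#' projected average capacity factor; per-class densities adjust nameplate
#' for class-specific capacity factors. Classes below the economic minimum
#' contribute 0 MW/km2.
#'
#' @slot referenceDensity MW/km2 at the reference capacity factor (5).
#' @slot referenceCapacityFactor projected average capacity factor (0.445);
#'   stored as metadata, not used to re-derive the per-class densities.
#' @slot densityByWpc named numeric, class (as character) -> MW/km2.
#' @aliases CapacityDensityTable
#' @exportClass CapacityDensityTable
setClass("CapacityDensityTable",
  representation(referenceDensity = "numeric",
                 referenceCapacityFactor = "numeric",
                 densityByWpc = "numeric"))

setValidity("CapacityDensityTable", function(object) {
  d <- object@densityByWpc
  if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d)))))
    return("densityByWpc must be named by integer wind power class")
  if (any(d <= 0)) return("densities must be strictly positive")
  if (is.unsorted(d[order(as.integer(names(d)))], strictly = TRUE))
    return("densities must be strictly increasing in wind power class")
  TRUE
})

#' Default capacity-density table
#'
#' MW/km2 by wind power class: 3 = 4.3, 4 = 4.8, 5 = 5.2, 6 = 5.5, 7 = 6.0;
#' classes 1-2 are below the economic minimum and contribute 0.
#'
#' @param densityByWpc named numeric override, class -> MW/km2.
#' @return a \linkS4class{CapacityDensityTable}.
#' @examples
#' capacityDensity(4, capacityDensityTable())  # 4.8
#' @export
capacityDensityTable <- function(densityByWpc = c("3" = 4.3, "4" = 4.8,
                                                  "5" = 5.2, "6" = 5.5,
                                                  "7" = 6.0)) {
  new("CapacityDensityTable", referenceDensity = 5,
      referenceCapacityFactor = 0.445, densityByWpc = densityByWpc)
}

# ---------------------------------------------------------------------------
# Synthetic-landscape parameters and container
# ---------------------------------------------------------------------------

#' LandscapeParams: parameters of the synthetic-landscape generator
#'
#' See \code{\link{landscapeParams}} for defaults and units.
#'
#' @aliases LandscapeParams
#' @exportClass LandscapeParams
setClass("LandscapeParams",
  representation(
    gridShape = "integer", cellSizeM = "numeric", seed = "integer",
    classProportions = "numeric", lcPatchScale = "numeric",
    nWells = "integer", wellClusterSd = "numeric", nHamlets = "integer",
    wpcRange = "integer", wpcCorrLength = "numeric",
    nCraneSites = "integer", craneObsPerSite = "integer",
    waterfowlDensityMean = "numeric", waterfowlDensitySd = "numeric",
    nPriorityPolygons = "integer",
    nTurbinesExisting = "integer", nTurbinesProposed = "integer"
  ))

setValidity("LandscapeParams", function(object) {
  msg <- character()
  chk <- function(cond, field)
    if (!cond) msg <<- c(msg, paste0("invalid field '", field, "'"))
  chk(length(object@gridShape) == 2L && all(object@gridShape >= 1L), "gridShape")
  chk(object@cellSizeM > 0, "cellSizeM")
  p <- object@classProportions
  chk(length(p) > 0 && all(p >= 0) && abs(sum(p) - 1) <= 1e-9 &&
        !is.null(names(p)), "classProportions")
  chk(object@lcPatchScale > 0, "lcPatchScale")
  chk(object@nWells >= 0L, "nWells")
  chk(object@wellClusterSd > 0, "wellClusterSd")
  chk(object@nHamlets >= 0L, "nHamlets")
  chk(length(object@wpcRange) == 2L && all(object@wpcRange >= 1L) &&
        all(object@wpcRange <= 7L) && object@wpcRange[1] <= object@wpcRange[2],
      "wpcRange")
  chk(object@wpcCorrLength > 0, "wpcCorrLength")
  chk(object@nCraneSites >= 0L, "nCraneSites")
  chk(length(object@craneObsPerSite) == 2L && all(object@craneObsPerSite >= 1L),
      "craneObsPerSite")
  chk(object@waterfowlDensityMean >= 0, "waterfowlDensityMean")
  chk(object@waterfowlDensitySd >= 0, "waterfowlDensitySd")
  chk(object@nPriorityPolygons >= 0L, "nPriorityPolygons")
  chk(object@nTurbinesExisting >= 0L, "nTurbinesExisting")
  chk(object@nTurbinesProposed >= 0L, "nTurbinesProposed")
  if (length(msg)) msg else TRUE
})

#' SyntheticLandscape: all generated layers of one synthetic study area
#'
#' Grids share shape and georeferencing; all vector features fall inside the
#' grid bounds. \code{layers()} (the \code{layers} slot) holds the
#' rule-resolvable layer map used by the exclusion engine.
#'
#' @slot landcover categorical land-cover grid (NLCD-style codes).
#' @slot impervious impervious-surface fraction grid (0-1).
#' @slot topoChange absolute topographic change grid (meters).
#' @slot wpc wind power class grid (integers 1-7).
#' @slot waterfowlDensity predicted waterfowl breeding pair density
#'   (pairs/km2).
#' @slot regions integer region-code grid; \code{regionNames} maps codes to
#'   labels.
#' @slot regionNames character vector naming region codes.
#' @slot wells,hamlets,craneObs,turbines point FeatureSets (craneObs carry
#'   ISO-8601 \code{date}; turbines carry \code{status} and \code{region}).
#' @slot roads,rivers line FeatureSets (rivers carry \code{name}).
#' @slot priorityPolygons,protectedAreas,sensitivityZones,urbanCores polygon
#'   FeatureSets (protectedAreas carry \code{gap_code}; sensitivityZones
#'   carry \code{category}).
#' @slot goals data.frame \code{region, goal_gw}.
#' @slot craneSiteTruth data.frame of ground-truth repeated-stopover labels.
#' @slot truthDisturbedLc ground-truth mask of cells the generator painted
#'   with a disturbed land-cover class.
#' @slot params the generating \linkS4class{LandscapeParams}.
#' @aliases SyntheticLandscape
#' @exportClass SyntheticLandscape
setClass("SyntheticLandscape",
  representation(
    landcover = "RasterGrid", impervious = "RasterGrid",
    topoChange = "RasterGrid", wpc = "RasterGrid",
    waterfowlDensity = "RasterGrid", regions = "RasterGrid",
    regionNames = "character",
    wells = "FeatureSet", hamlets = "FeatureSet",
    craneObs = "FeatureSet", turbines = "FeatureSet",
    roads = "FeatureSet", rivers = "FeatureSet",
    priorityPolygons = "FeatureSet", protectedAreas = "FeatureSet",
    sensitivityZones = "FeatureSet", urbanCores = "FeatureSet",
    goals = "data.frame", craneSiteTruth = "data.frame",
    truthDisturbedLc = "BinaryMask",
    params = "LandscapeParams"
  ))

setValidity("SyntheticLandscape", function(object) {
  msg <- character()
  ref <- object@landcover
  for (nm in c("impervious", "topoChange", "wpc", "waterfowlDensity",
               "regions")) {
    g <- slot(object, nm)
    if (!identical(dim(g@values), dim(ref@values)) ||
        !isTRUE(all.equal(c(g@xmin, g@ymin, g@cellSize),
                          c(ref@xmin, ref@ymin, ref@cellSize))) ||
        g@crs != ref@crs)
      msg <- c(msg, paste0("grid '", nm, "' not aligned with landcover"))
  }
  b <- c(ref@xmin, ref@xmin + ncol(ref@values) * ref@cellSize,
         ref@ymin, ref@ymin + nrow(ref@values) * ref@cellSize)
  for (nm in c("wells", "hamlets", "craneObs", "turbines", "roads", "rivers",
               "priorityPolygons", "protectedAreas", "sensitivityZones",
               "urbanCores")) {
    fs <- slot(object, nm)
    for (g in fs@geoms)
      if (any(g[, 1] < b[1] | g[, 1] > b[2] | g[, 2] < b[3] | g[, 2] > b[4])) {
        msg <- c(msg, paste0("features in '", nm, "' fall outside grid bounds"))
        break
      }
  }
  if (nFeaturesInternal(object@craneObs) > 0) {
    d <- object@craneObs@attrs$date
    if (is.null(d) || anyNA(as.Date(d, format = "%Y-%m-%d")))
      msg <- c(msg, "every crane observation needs a valid ISO-8601 date")
  }
  if (length(msg)) msg else TRUE
})

# internal helper usable before accessors are defined
nFeaturesInternal <- function(fs) length(fs@geoms)
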