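#' @include disturbance.R
NULL

#' Identify repeated whooping-crane stopover sites
#'
#' Observations are clustered into sites by single-linkage within
#' \code{siteRadius}; a site is a repeated stopover if its observations span
#' at least two distinct calendar years, or include three or more distinct
#' days within a single year.
#'
#' @param observations point \linkS4class{FeatureSet} with an ISO-8601
#'   \code{date} attribute.
#' @param siteRadius clustering distance, meters: observations closer than
#'   this (single linkage) belong to one site.
#' @return point \linkS4class{FeatureSet} with one representative point
#'   (observation centroid) per qualifying site, and attributes
#'   \code{n_obs}, \code{n_years}, \code{max_days_one_year}.
#' @export
repeatedStopoverSites <- function(observations, siteRadius) {
  n <- nFeatures(observations)
  if (n == 0L)
    return(featureSet("point", crs = observations@crs))
  dates <- featureAttrs(observations)$date
  if (is.null(dates))
    stop("data error: observations carry no 'date' attribute", call. = FALSE)
  parsed <- as.Date(dates, format = "%Y-%m-%d")
  if (anyNA(parsed))
    stop("data error: unparseable date in observation record(s) ",
         paste(which(is.na(parsed)), collapse = ", "), call. = FALSE)
  xy <- pointCoords(observations)
  cl <- if (n == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(xy), method = "single"),
                  h = siteRadius)
  keep <- list(); attrs <- list()
  for (s in sort(unique(cl))) {
    i <- which(cl == s)
    yrs <- as.integer(format(parsed[i], "%Y"))
    daysPerYear <- tapply(parsed[i], yrs, function(d) length(unique(d)))
    qualifies <- length(unique(yrs)) >= 2L || any(daysPerYear >= 3L)
    if (qualifies) {
      keep[[length(keep) + 1L]] <-
        matrix(colMeans(xy[i, , drop = FALSE]), 1, 2)
      attrs[[length(attrs) + 1L]] <-
        data.frame(n_obs = length(i), n_years = length(unique(yrs)),
                   max_days_one_year = max(daysPerYear))
    }
  }
  featureSet("point", keep,
             if (length(attrs)) do.call(rbind, attrs) else data.frame(),
             observations@crs)
}

# attribute filter: params$where = list(attr = "gap_code", values = c(1, 2))
applyWhere <- function(fs, where) {
  if (is.null(where)) return(fs)
  vals <- featureAttrs(fs)[[where$attr]]
  if (is.null(vals))
    stop("configuration error: filter attribute '", where$attr,
         "' not present in layer", call. = FALSE)
  subsetFeatures(fs, vals %in% unlist(where$values))
}

#' Burn polygons to a mask
#'
#' Cells whose center falls inside any polygon (even-odd rule) are 1.
#'
#' @param polygons polygon \linkS4class{FeatureSet}.
#' @param template analysis \linkS4class{RasterGrid}.
#' @return a \linkS4class{BinaryMask}.
#' @export
polygonBurnMask <- function(polygons, template) {
  d <- dim(template@values)
  hit <- matrix(FALSE, d[1], d[2])
  cs <- template@cellSize
  b <- gridBounds(template)
  xs <- template@xmin + (seq_len(d[2]) - 0.5) * cs
  ys <- b["ymax"] - (seq_len(d[1]) - 0.5) * cs
  for (ring in featureCoords(polygons)) {
    jr <- which(xs >= min(ring[, 1]) - cs & xs <= max(ring[, 1]) + cs)
    ir <- which(ys >= min(ring[, 2]) - cs & ys <= max(ring[, 2]) + cs)
    if (!length(jr) || !length(ir)) next
    px <- rep(xs[jr], each = length(ir))
    py <- rep(ys[ir], times = length(jr))
    inside <- pointsInRing(px, py, ring)
    hit[ir, jr] <- hit[ir, jr] | matrix(inside, length(ir), length(jr))
  }
  binaryMask(hit, template, provenance = "polygon_burn")
}

#' Cells within a buffer of line features
#'
#' @param lines line \linkS4class{FeatureSet}.
#' @param template analysis \linkS4class{RasterGrid}.
#' @param radius buffer radius, meters (cell-center distance).
#' @return a \linkS4class{BinaryMask}.
#' @export
lineBufferMask <- function(lines, template, radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  cc <- cellCenters(template)
  d <- dim(template@values)
  hit <- matrix(FALSE, d[1], d[2])
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  for (g in featureCoords(lines))
    hit <- hit | matrix(distToPolyline(px, py, g) <= radius, d[1], d[2])
  binaryMask(hit, template, provenance = "line_buffer")
}

# category rules accept either a categorical grid or polygons carrying a
# `category` attribute (burn the qualifying polygons)
categoryRuleMask <- function(layer, template, qualifies) {
  if (is(layer, "RasterGrid")) {
    v <- layer@values
    m <- matrix(as.double(qualifies(v)), nrow(v), ncol(v))
    m[is.na(v)] <- NA_real_
    binaryMask(m, template)
  } else if (is(layer, "FeatureSet") && geomType(layer) == "polygon") {
    cat <- featureAttrs(layer)$category
    if (is.null(cat))
      stop("configuration error: polygon layer lacks 'category' attribute",
           call. = FALSE)
    polygonBurnMask(subsetFeatures(layer, qualifies(cat)), template)
  } else {
    stop("configuration error: category rule needs a grid or polygon layer",
         call. = FALSE)
  }
}

#' Compile one exclusion rule to a mask
#'
#' @param rule an \linkS4class{ExclusionRule}.
#' @param layers named list of \linkS4class{RasterGrid} /
#'   \linkS4class{FeatureSet} input layers.
#' @param template analysis \linkS4class{RasterGrid}.
#' @return a \linkS4class{BinaryMask} with the rule id as provenance.
#' @export
compileRule <- function(rule, layers, template) {
  layer <- layers[[rule@source]]
  if (is.null(layer))
    stop("configuration error: rule '", rule@ruleId, "' needs layer '",
         rule@source, "', which is not provided", call. = FALSE)
  p <- rule@params
  needFS <- function(kind) {
    if (!is(layer, "FeatureSet") || geomType(layer) != kind)
      stop("configuration error: rule '", rule@ruleId, "' expects a ", kind,
           " layer in '", rule@source, "'", call. = FALSE)
    applyWhere(layer, p$where)
  }
  m <- switch(rule@operator,
    polygon_burn = polygonBurnMask(needFS("polygon"), template),
    category_at_least = categoryRuleMask(layer, template,
                                         function(v) v >= p$threshold),
    category_in_set = categoryRuleMask(layer, template,
                                       function(v) v %in% unlist(p$categories)),
    density_at_least = {
      if (!is(layer, "RasterGrid"))
        stop("configuration error: rule '", rule@ruleId,
             "' expects a grid layer in '", rule@source, "'", call. = FALSE)
      v <- layer@values
      mm <- matrix(as.double(v >= p$threshold), nrow(v), ncol(v))
      mm[is.na(v)] <- NA_real_
      binaryMask(mm, template)
    },
    point_buffer = pointBufferMask(needFS("point"), template, p$radius),
    line_buffer = lineBufferMask(needFS("line"), template, p$radius),
    repeated_stopover_buffer = {
      obs <- needFS("point")
      siteRadius <- if (is.null(p$site_radius)) template@cellSize
                    else p$site_radius
      sites <- repeatedStopoverSites(obs, siteRadius)
      pointBufferMask(sites, template, p$radius)
    },
    stop("configuration error: unknown operator '", rule@operator, "'",
         call. = FALSE))
  m@provenance <- rule@ruleId
  m
}

#' Compose a jurisdiction's exclusion mask
#'
#' Union of all compiled rule masks; provenance records every contributing
#' rule id. Compilation failures abort naming the offending rule.
#'
#' @param ruleset a \linkS4class{RuleSet}.
#' @param layers named list of input layers.
#' @param template analysis \linkS4class{RasterGrid}.
#' @return a \linkS4class{BinaryMask}.
#' @export
composeExclusions <- function(ruleset, layers, template) {
  if (!length(ruleset@rules))
    return(binaryMask(matrix(FALSE, nrow(template@values),
                             ncol(template@values)), template))
  masks <- lapply(ruleset@rules, function(r)
    tryCatch(compileRule(r, layers, template),
             error = function(e)
               stop("rule '", r@ruleId, "' failed: ", conditionMessage(e),
                    call. = FALSE)))
  unionMasks(masks)
}

# --- YAML serialization ----------------------------------------------------

#' Read a rule set from YAML
#'
#' @param path YAML file with fields \code{jurisdiction} and \code{rules}
#'   (each rule: \code{rule_id}, \code{source}, \code{operator},
#'   \code{params}).
#' @return a \linkS4class{RuleSet}.
#' @export
readRuleSet <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules, function(r) {
    params <- if (is.null(r$params)) list() else r$params
    do.call(exclusionRule,
            c(list(ruleId = r$rule_id, source = r$source,
                   operator = r$operator), params))
  })
  ruleSet(y$jurisdiction, rules)
}

#' Write a rule set to YAML
#' @param ruleset a \linkS4class{RuleSet}.
#' @param path output file.
#' @export
writeRuleSet <- function(ruleset, path) {
  y <- list(
    jurisdiction = ruleset@jurisdiction,
    rules = lapply(ruleset@rules, function(r)
      list(rule_id = r@ruleId, source = r@source, operator = r@operator,
           params = r@params)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load one of the shipped jurisdiction rule sets
#'
#' Shipped sets: \code{ab_sk} (Alberta & Saskatchewan: important bird
#' areas, conservancy priority areas), \code{mt} (Montana: crucial-areas
#' category layers, sage-grouse cores, priority areas), \code{ne}
#' (Nebraska: 1-6 sensitivity ranking top four categories, playa lakes),
#' \code{nd_sd} (the Dakotas: waterfowl pair density >= 104 pairs/km2,
#' priority areas, repeated crane stopovers buffered 3.2 km, 1.6 km
#' Missouri/Red river corridors), \code{wy} (Wyoming: wildlife action plan
#' priorities, ungulate corridors and ranges, sage-grouse cores, wetland
#' complexes).
#'
#' @param name jurisdiction key, one of \code{ab_sk, mt, ne, nd_sd, wy}.
#' @return a \linkS4class{RuleSet}.
#' @export
shippedRuleSet <- function(name = c("ab_sk", "mt", "ne", "nd_sd", "wy")) {
  name <- match.arg(name)
  path <- system.file("rulesets", paste0(name, ".yaml"),
                      package = "windsift", mustWork = TRUE)
  readRuleSet(path)
}

#' @export
setMethod("jurisdiction", "RuleSet", function(x) x@jurisdiction)

#' @export
setMethod("rules", "RuleSet", function(x) x@rules)

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet '", object@jurisdiction, "': ", length(object@rules),
      " rule(s)\n", sep = "")
  for (r in object@rules)
    cat("  -", r@ruleId, ":", r@operator, "on", r@source, "\n")
})
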