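#' @include io.R
NULL

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full low-impact siting pipeline
#'
#' Composes the disturbance footprint, applies the patch-size/isolation
#' filter, compiles the jurisdiction's wildlife exclusions, intersects
#' with wind viability and subtracts protected areas, urban cores and
#' water, then converts the surviving low-impact mask to GW per region and
#' audits turbine locations against it. Deterministic given its inputs.
#'
#' @param layers named list of input layers (as from
#'   \code{\link{landscapeLayers}}); must contain \code{landcover} and
#'   \code{wpc}, and may contain \code{impervious}, \code{topo_change},
#'   \code{wells}, \code{roads}, \code{hamlets}, \code{protected_areas},
#'   \code{urban_cores}, \code{turbines}, plus whatever the rule set
#'   references.
#' @param ruleset a \linkS4class{RuleSet} (or jurisdiction key resolved via
#'   \code{\link{shippedRuleSet}}).
#' @param goals data.frame \code{region, goal_gw}.
#' @param regions region-code \linkS4class{RasterGrid} (integer codes) or
#'   polygon FeatureSet with \code{region} attribute.
#' @param regionNames names of integer region codes (grid regions only).
#' @param outDir optional output directory; when given, writes
#'   \code{low_impact.asc}, \code{region_summary.csv},
#'   \code{turbine_summary.csv} and \code{provenance.json}.
#' @param disturbance a \code{\link{disturbanceConfig}}.
#' @param suitability a \code{\link{suitabilityConfig}}.
#' @param minPatchKm2,maxIsolationM,connectivity patch-filter parameters.
#' @param capacityTable a \linkS4class{CapacityDensityTable}.
#' @param seed recorded in provenance (the pipeline itself draws no
#'   random numbers).
#' @return list with masks (\code{disturbed}, \code{filtered},
#'   \code{exclusions}, \code{viability}, \code{lowImpact}), the region
#'   and turbine summaries, and the provenance record.
#' @export
runPipeline <- function(layers, ruleset, goals, regions,
                        regionNames = NULL, outDir = NULL,
                        disturbance = disturbanceConfig(),
                        suitability = suitabilityConfig(),
                        minPatchKm2 = 1, maxIsolationM = 800,
                        connectivity = 8,
                        capacityTable = capacityDensityTable(),
                        seed = NULL) {
  if (is.character(ruleset)) ruleset <- shippedRuleSet(ruleset)
  template <- layers$landcover
  if (is.null(template)) stop("layers must contain 'landcover'",
                              call. = FALSE)
  if (is.null(layers$wpc)) stop("layers must contain 'wpc'", call. = FALSE)

  disturbed <- stage("disturbance",
    disturbanceMask(layers$landcover, layers$impervious,
                    layers$topo_change, layers$wells, layers$roads,
                    layers$hamlets, disturbance))
  filtered <- stage("patch_filter",
    filterSmallIsolated(disturbed, minPatchKm2, maxIsolationM, connectivity))
  exclusions <- stage("exclusions",
    composeExclusions(ruleset, layers, template))
  viability <- stage("wind_viability",
    windViabilityMask(layers$wpc, suitability$minWpc))
  protected <- stage("protected_areas",
    if (!is.null(layers$protected_areas))
      compileRule(exclusionRule("gap_protected", "protected_areas",
                                "polygon_burn",
                                where = list(attr = "gap_code",
                                             values = suitability$gapExcludeCodes)),
                  layers, template)
    else binaryMask(matrix(FALSE, nrow(template@values),
                           ncol(template@values)), template))
  urban <- stage("urban_cores",
    if (!is.null(layers$urban_cores))
      polygonBurnMask(layers$urban_cores, template)
    else binaryMask(matrix(FALSE, nrow(template@values),
                           ncol(template@values)), template))
  water <- stage("water",
    landcoverMask(layers$landcover, suitability$waterLcCodes))
  lowImpact <- stage("candidate",
    candidateMask(filtered, exclusions, viability, protected, urban, water))

  perRegion <- stage("capacity",
    aggregateCapacity(lowImpact, layers$wpc, regions, capacityTable,
                      regionNames))
  regionSummary <- stage("capacity", summarizeRegions(perRegion, goals))

  turbineSummary <- NULL
  classified <- NULL
  if (!is.null(layers$turbines) && nFeatures(layers$turbines) > 0) {
    classified <- stage("turbines",
                        classifyTurbines(layers$turbines, lowImpact))
    turbineSummary <- stage("turbines", summarizeTurbines(classified))
  }

  prov <- list(
    jurisdiction = ruleset@jurisdiction,
    rules = lapply(ruleset@rules, function(r)
      list(rule_id = r@ruleId, source = r@source, operator = r@operator,
           params = r@params)),
    disturbance = unclass(disturbance),
    suitability = unclass(suitability),
    patch_filter = list(min_area_km2 = minPatchKm2,
                        max_isolation_m = maxIsolationM,
                        connectivity = connectivity),
    capacity_density = as.list(capacityTable@densityByWpc),
    seed = seed,
    low_impact_provenance = lowImpact@provenance)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAsciiGrid(lowImpact, file.path(outDir, "low_impact.asc"))
    utils::write.csv(regionSummary, file.path(outDir, "region_summary.csv"),
                     row.names = FALSE)
    if (!is.null(turbineSummary))
      utils::write.csv(turbineSummary,
                       file.path(outDir, "turbine_summary.csv"),
                       row.names = FALSE)
    outFiles <- list.files(outDir, full.names = TRUE)
    prov$output_checksums <- as.list(tools::md5sum(outFiles))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(disturbed = disturbed, filtered = filtered, exclusions = exclusions,
       viability = viability, protected = protected, urban = urban,
       water = water, lowImpact = lowImpact,
       regionSummary = regionSummary, turbineSummary = turbineSummary,
       classifiedTurbines = classified, provenance = prov)
}

#' Run the pipeline on a synthetic landscape
#'
#' Convenience wrapper: resolves the layer map, goals and regions from a
#' \linkS4class{SyntheticLandscape} and calls \code{\link{runPipeline}}.
#'
#' @param landscape a \linkS4class{SyntheticLandscape}.
#' @param ruleset a \linkS4class{RuleSet} or jurisdiction key
#'   (default \code{"nd_sd"}).
#' @param ... passed on to \code{\link{runPipeline}}.
#' @return see \code{\link{runPipeline}}.
#' @export
runLandscapePipeline <- function(landscape, ruleset = "nd_sd", ...) {
  runPipeline(landscapeLayers(landscape), ruleset, landscape@goals,
              landscape@regions, landscape@regionNames,
              seed = landscape@params@seed, ...)
}

#' Run the pipeline from a YAML configuration file
#'
#' The config maps layer names to files (\code{.asc} grids, \code{.geojson}
#' vectors), names a goals CSV, a jurisdiction (or rule-set YAML path) and
#' an output directory. Paths are resolved relative to the config file.
#'
#' @param configPath YAML file with fields \code{layers} (name -> path),
#'   \code{goals}, \code{regions} (an .asc path),
#'   \code{region_names} (optional), \code{jurisdiction} or
#'   \code{ruleset}, \code{out}, and optional \code{params} overrides
#'   (\code{min_wpc}, \code{min_patch_km2}, \code{max_isolation_m},
#'   \code{kde_bandwidth}, \code{kde_threshold}, \code{hamlet_buffer}).
#' @return see \code{\link{runPipeline}}.
#' @export
runPipelineConfig <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  base <- dirname(normalizePath(configPath))
  rel <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p) || file.exists(p)) p
    else file.path(base, p)
  }
  layers <- lapply(cfg$layers, function(p) {
    p <- rel(p)
    if (grepl("\\.asc$", p, ignore.case = TRUE)) readAsciiGrid(p)
    else readGeoJSON(p)
  })
  goals <- utils::read.csv(rel(cfg$goals))
  regions <- readAsciiGrid(rel(cfg$regions))
  ruleset <- if (!is.null(cfg$ruleset)) readRuleSet(rel(cfg$ruleset))
             else cfg$jurisdiction
  pr <- cfg$params
  runPipeline(layers, ruleset, goals, regions,
              regionNames = unlist(cfg$region_names),
              outDir = rel(cfg$out),
              disturbance = disturbanceConfig(
                kdeBandwidth = pr$kde_bandwidth %||% 1000,
                kdeThreshold = pr$kde_threshold %||% 1,
                hamletBuffer = pr$hamlet_buffer %||% 300),
              suitability = suitabilityConfig(
                minWpc = pr$min_wpc %||% 3L),
              minPatchKm2 = pr$min_patch_km2 %||% 1,
              maxIsolationM = pr$max_isolation_m %||% 800,
              seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
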