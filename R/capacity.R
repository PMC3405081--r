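#' @include patches.R
NULL

#' Installable capacity density for one wind power class
#'
#' @param wpc integer wind power class in [1, 7].
#' @param table a \linkS4class{CapacityDensityTable}.
#' @return MW/km2 (0 for classes below the table's minimum).
#' @examples
#' capacityDensity(3)  # 4.3
#' capacityDensity(2)  # 0
#' @export
capacityDensity <- function(wpc, table = capacityDensityTable()) {
  if (any(is.na(wpc)) || any(wpc < 1 | wpc > 7 | wpc != round(wpc)))
    stop("data error: wind power class must be an integer in [1, 7]",
         call. = FALSE)
  d <- table@densityByWpc[as.character(wpc)]
  d[is.na(d)] <- 0
  unname(d)
}

#' Round half away from zero
#'
#' Integer rounding used for the printed percent columns (2642.6 -> 2643).
#' @param x numeric.
#' @export
roundHalfUp <- function(x) trunc(x + 0.5 * sign(x))

#' Aggregate low-impact capacity by region
#'
#' GW per region: the sum over low-impact cells of cell area (km2) times
#' the capacity density of the cell's wind power class, divided by 1000.
#' Low-impact cells with missing wind class contribute 0 and are counted
#' in the \code{n_nodata_wpc} attribute.
#'
#' @param lowImpact \linkS4class{BinaryMask} of low-impact cells.
#' @param wpc aligned wind power class \linkS4class{RasterGrid}.
#' @param regions aligned integer region-code \linkS4class{RasterGrid}, or
#'   a polygon \linkS4class{FeatureSet} with a \code{region} attribute.
#' @param table a \linkS4class{CapacityDensityTable}.
#' @param regionNames optional character vector naming integer region codes.
#' @return data.frame \code{region, low_impact_gw} (one row per region,
#'   sorted by region), with attribute \code{n_nodata_wpc}.
#' @export
aggregateCapacity <- function(lowImpact, wpc, regions,
                              table = capacityDensityTable(),
                              regionNames = NULL) {
  stopIfMisaligned(lowImpact, wpc, what = "capacity inputs")
  if (is(regions, "FeatureSet")) {
    regGrid <- matrix(NA_real_, nrow(lowImpact@values), ncol(lowImpact@values))
    cc <- cellCenters(lowImpact)
    regs <- featureAttrs(regions)$region
    if (is.null(regs))
      stop("configuration error: region polygons need a 'region' attribute",
           call. = FALSE)
    codes <- seq_along(regs)
    for (i in codes) {
      inside <- pointsInRing(as.vector(cc$x), as.vector(cc$y),
                             featureCoords(regions)[[i]])
      regGrid[matrix(inside, nrow(regGrid), ncol(regGrid))] <- i
    }
    regionNames <- as.character(regs)
  } else {
    stopIfMisaligned(lowImpact, regions, what = "capacity inputs")
    regGrid <- regions@values
  }
  li <- lowImpact@values
  sel <- !is.na(li) & li == 1 & !is.na(regGrid)
  w <- wpc@values
  nNodata <- sum(sel & is.na(w))
  if (nNodata > 0)
    message(nNodata, " low-impact cell(s) have no wind power class; ",
            "counted at 0 MW/km2")
  dens <- rep(0, sum(sel))
  okW <- !is.na(w[sel])
  if (any(okW)) dens[okW] <- capacityDensity(w[sel][okW], table)
  gw <- tapply(cellAreaKm2(lowImpact) * dens / 1000, regGrid[sel], sum)
  codesPresent <- as.integer(names(gw))
  labels <- if (!is.null(regionNames)) regionNames[codesPresent]
            else as.character(codesPresent)
  out <- data.frame(region = labels, low_impact_gw = as.numeric(gw))
  out <- out[order(out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nodata_wpc") <- nNodata
  out
}

#' Percent of a development goal
#'
#' Integer percent (rounded half away from zero) of \code{lowImpactGw}
#' relative to \code{goalGw}, computed on unrounded GW.
#'
#' @param lowImpactGw achievable capacity, GW.
#' @param goalGw development goal, GW (> 0).
#' @return integer percent.
#' @examples
#' percentOfGoal(139, 5.26)   # 2643
#' percentOfGoal(254, 2.26)   # 11239
#' @export
percentOfGoal <- function(lowImpactGw, goalGw) {
  if (any(goalGw <= 0))
    stop("parameter error: goalGw must be > 0", call. = FALSE)
  as.integer(roundHalfUp(100 * lowImpactGw / goalGw))
}

#' Regional capacity summary with total row
#'
#' One row per region (goal, achievable low-impact GW, percent of goal)
#' plus a Total row whose goal and GW are sums and whose percent is
#' computed from the summed, unrounded values.
#'
#' @param perRegionGw data.frame \code{region, low_impact_gw} (as returned
#'   by \code{\link{aggregateCapacity}}).
#' @param goals data.frame \code{region, goal_gw}; every region in
#'   \code{perRegionGw} must appear.
#' @return data.frame \code{region, goal_gw, low_impact_gw, pct_of_goal}.
#' @export
summarizeRegions <- function(perRegionGw, goals) {
  missing <- setdiff(perRegionGw$region, goals$region)
  if (length(missing))
    stop("configuration error: no development goal for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  # regions with a goal but no surviving low-impact area report 0 GW
  m <- merge(goals, perRegionGw, by = "region", all.x = TRUE, sort = TRUE)
  m$low_impact_gw[is.na(m$low_impact_gw)] <- 0
  out <- data.frame(region = m$region, goal_gw = m$goal_gw,
                    low_impact_gw = m$low_impact_gw,
                    pct_of_goal = percentOfGoal(m$low_impact_gw, m$goal_gw))
  total <- data.frame(region = "Total", goal_gw = sum(m$goal_gw),
                      low_impact_gw = sum(m$low_impact_gw),
                      pct_of_goal = percentOfGoal(sum(m$low_impact_gw),
                                                  sum(m$goal_gw)))
  rbind(out, total)
}
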