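#' @include capacity.R
NULL

#' Classify turbine locations against the low-impact mask
#'
#' Each turbine point takes the value of the mask cell containing it
#' (half-open cell convention: a cell owns its top and left edges).
#' Out-of-bounds points are flagged, not dropped: they get
#' \code{in_low_impact = FALSE}, \code{out_of_bounds = TRUE} and a warning.
#'
#' @param turbines point \linkS4class{FeatureSet} (typically with
#'   \code{status} and \code{region} attributes).
#' @param lowImpact a \linkS4class{BinaryMask}.
#' @return the input FeatureSet with logical attributes
#'   \code{in_low_impact} and \code{out_of_bounds} appended.
#' @export
classifyTurbines <- function(turbines, lowImpact) {
  n <- nFeatures(turbines)
  attrs <- featureAttrs(turbines)
  if (n == 0L) {
    attrs$in_low_impact <- logical(0)
    attrs$out_of_bounds <- logical(0)
    return(featureSet("point", list(), attrs, turbines@crs))
  }
  xy <- pointCoords(turbines)
  idx <- pointToCell(lowImpact, xy[, 1], xy[, 2])
  oob <- is.na(idx$row)
  inLI <- rep(FALSE, n)
  if (any(!oob)) {
    v <- lowImpact@values[cbind(idx$row[!oob], idx$col[!oob])]
    inLI[!oob] <- !is.na(v) & v == 1
  }
  if (any(oob))
    warning(sum(oob), " turbine(s) outside the grid; classified as not ",
            "low-impact", call. = FALSE)
  attrs$in_low_impact <- inLI
  attrs$out_of_bounds <- oob
  featureSet("point", featureCoords(turbines), attrs, turbines@crs)
}

#' Summarize turbine siting by region and status
#'
#' Counts and integer-rounded percentages of turbines falling in low-impact
#' areas, per region and status, plus one Total row per status whose counts
#' are summed before the percent is computed.
#'
#' @param classified output of \code{\link{classifyTurbines}}; every
#'   turbine must carry \code{region} and \code{status} attributes
#'   (status in \code{existing}, \code{proposed}).
#' @return data.frame \code{region, status, n_turbines, n_low_impact,
#'   pct_low_impact}.
#' @export
summarizeTurbines <- function(classified) {
  a <- featureAttrs(classified)
  if (is.null(a$region) || is.null(a$status))
    stop("data error: turbines need 'region' and 'status' attributes",
         call. = FALSE)
  if (!all(a$status %in% c("existing", "proposed")))
    stop("data error: turbine status must be 'existing' or 'proposed'",
         call. = FALSE)
  summarizeTurbineCounts(stats::aggregate(
    cbind(n_turbines = rep(1L, nrow(a)),
          n_low_impact = as.integer(a$in_low_impact)) ~ region + status,
    data = a, FUN = sum))
}

#' Turbine summary from pre-tabulated counts
#'
#' The arithmetic core of \code{\link{summarizeTurbines}}, usable directly
#' on a published count table.
#'
#' @param counts data.frame \code{region, status, n_turbines, n_low_impact}.
#' @return data.frame with \code{pct_low_impact} and per-status Total rows
#'   appended.
#' @export
summarizeTurbineCounts <- function(counts) {
  stopifnot(all(c("region", "status", "n_turbines", "n_low_impact") %in%
                  names(counts)))
  if (any(counts$n_low_impact > counts$n_turbines) ||
      any(counts$n_low_impact < 0))
    stop("data error: 0 <= n_low_impact <= n_turbines violated",
         call. = FALSE)
  counts <- counts[order(counts$status, counts$region), , drop = FALSE]
  pct <- function(k, n) ifelse(n > 0, as.integer(roundHalfUp(100 * k / n)), 0L)
  counts$pct_low_impact <- pct(counts$n_low_impact, counts$n_turbines)
  totals <- do.call(rbind, lapply(split(counts, counts$status), function(g)
    data.frame(region = "Total", status = g$status[1],
               n_turbines = sum(g$n_turbines),
               n_low_impact = sum(g$n_low_impact),
               pct_low_impact = pct(sum(g$n_low_impact),
                                    sum(g$n_turbines)))))
  out <- rbind(counts, totals)
  rownames(out) <- NULL
  out
}
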