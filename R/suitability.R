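#' @include exclusions.R
NULL

#' Suitability configuration
#'
#' @param minWpc minimum economically viable wind power class (default 3,
#'   i.e. mean annual wind speed >= 6.4 m/s at 50 m).
#' @param waterLcCodes land-cover codes excluded as wetlands/water.
#' @param gapExcludeCodes protected-area GAP status codes excluded
#'   (default 1-2: permanent protection prohibiting development).
#' @return validated list of class \code{SuitabilityConfig}.
#' @export
suitabilityConfig <- function(minWpc = 3L,
                              waterLcCodes = waterLandcoverCodes(),
                              gapExcludeCodes = c(1L, 2L)) {
  if (!(minWpc >= 1 && minWpc <= 7))
    stop("minWpc must lie in [1, 7]", call. = FALSE)
  structure(list(minWpc = as.integer(minWpc),
                 waterLcCodes = as.integer(waterLcCodes),
                 gapExcludeCodes = as.integer(gapExcludeCodes)),
            class = "SuitabilityConfig")
}

#' Economically viable wind mask
#'
#' Cells with wind power class at or above \code{minWpc} are viable.
#'
#' @param wpc wind power class \linkS4class{RasterGrid} (integers 1-7).
#' @param minWpc minimum viable class (default 3).
#' @return a \linkS4class{BinaryMask}.
#' @export
windViabilityMask <- function(wpc, minWpc = 3L) {
  v <- wpc@values
  bad <- !is.na(v) & (v < 1 | v > 7 | v != round(v))
  if (any(bad))
    stop("data error: wind power class values must be integers in [1, 7]",
         call. = FALSE)
  m <- matrix(as.double(v >= minWpc), nrow(v), ncol(v))
  m[is.na(v)] <- NA_real_
  binaryMask(m, wpc, provenance = "wind_viability")
}

#' Pre-filter low-impact candidate mask
#'
#' A cell is a candidate iff it is disturbed, has viable wind, and is
#' outside the wildlife-exclusion, protected-area, urban-core and
#' water masks. Nodata in a subtracted mask is treated as "not excluded";
#' nodata in disturbance or viability propagates as 0.
#'
#' @param disturbed,exclusions,viability,protected,urban,water aligned
#'   \linkS4class{BinaryMask} objects.
#' @return a \linkS4class{BinaryMask}.
#' @export
candidateMask <- function(disturbed, exclusions, viability, protected,
                          urban, water) {
  stopIfMisaligned(disturbed, exclusions, viability, protected, urban, water,
                   what = "candidate-mask inputs")
  pos <- function(m) { v <- m@values; v[is.na(v)] <- 0; v }
  out <- pos(disturbed) * pos(viability) *
    (1 - pos(exclusions)) * (1 - pos(protected)) *
    (1 - pos(urban)) * (1 - pos(water))
  binaryMask(out, disturbed,
             provenance = c(disturbed@provenance, viability@provenance,
                            paste0("not:", c(exclusions@provenance,
                                             protected@provenance,
                                             urban@provenance,
                                             water@provenance))))
}
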