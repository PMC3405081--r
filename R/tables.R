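#' @include pipeline.R
NULL

#' Published Northern Great Plains regional capacity inputs
#'
#' Per-state/province development goals (GW) and reported achievable GW on
#' low-impact disturbed lands for the seven NGP jurisdictions, as shipped
#' with the package. These are inputs to the percent-of-goal arithmetic:
#' \code{\link{summarizeRegions}} on this table reproduces the regional
#' summary, including the Total row (29.95 GW goal, 1,056 GW achievable).
#'
#' @return data.frame \code{region, goal_gw, low_impact_gw}.
#' @examples
#' t1 <- ngpCapacityInputs()
#' summarizeRegions(t1[, c("region", "low_impact_gw")],
#'                  t1[, c("region", "goal_gw")])
#' @export
ngpCapacityInputs <- function() {
  utils::read.csv(system.file("extdata", "ngp_capacity_table.csv",
                              package = "windsift", mustWork = TRUE),
                  check.names = FALSE)
}

#' Published Northern Great Plains turbine siting counts
#'
#' Existing and proposed turbine counts per jurisdiction, with the number
#' falling inside low-impact areas. \code{\link{summarizeTurbineCounts}}
#' on this table reproduces the published siting percentages (34% of
#' existing and 30% of proposed turbines in low-impact areas).
#'
#' @return data.frame \code{region, status, n_turbines, n_low_impact}.
#' @export
ngpTurbineCounts <- function() {
  utils::read.csv(system.file("extdata", "ngp_turbine_counts.csv",
                              package = "windsift", mustWork = TRUE),
                  check.names = FALSE)
}
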