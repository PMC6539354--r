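#' The packaged two-stage production / health-treatment configuration
#'
#' A ready-made [dea_spec()] for a two-stage process: a *production* stage
#' with labor and energy consumption as inputs and GDP as the desirable
#' output, passing CO2 emissions and the air quality index (AQI) as link
#' variables into a *health treatment* stage, which uses health expenditure
#' and media reports as inputs and produces the birth rate (desirable)
#' together with respiratory diseases and the mortality rate (undesirable).
#' Fixed-asset investment is the good carry-over connecting consecutive
#' periods.
#'
#' The carry-over attaches to the production stage by default — capital
#' stock is a production-side quantity — but can be moved to the health
#' stage with `carryover_division = 2`.
#'
#' @param carryover_division 1 (production, default) or 2 (health
#'   treatment): which stage holds the fixed-assets carry-over.
#' @param period_weights,division_weights Passed to [dea_spec()].
#' @return A validated `dndea_spec` with divisions `production` and
#'   `health_treatment`.
#' @examples
#' spec <- two_stage_spec()
#' spec$dims
#' @export
two_stage_spec <- function(carryover_division = 1,
                           period_weights = NULL, division_weights = NULL) {
  if (!carryover_division %in% c(1, 2))
    stop("`carryover_division` must be 1 or 2", call. = FALSE)
  dnames <- c("production", "health_treatment")
  dea_spec(
    divisions = list(
      production = list(
        inputs = c("labor", "energy_consumption"),
        good_outputs = "gdp"),
      health_treatment = list(
        inputs = c("health_expenditure", "media_reports"),
        good_outputs = "birth_rate",
        bad_outputs = c("respiratory_diseases", "mortality_rate"))),
    links = data.frame(
      source = "production", target = "health_treatment",
      variable = c("co2", "aqi"), stringsAsFactors = FALSE),
    carryovers = data.frame(
      division = dnames[carryover_division], variable = "fixed_assets",
      stringsAsFactors = FALSE),
    period_weights = period_weights,
    division_weights = division_weights)
}

#' Run the two-stage model end to end
#'
#' Convenience driver: validates the panel against the two-stage
#' configuration, solves every DMU, and returns the fitted [dndea()] model
#' (overall/period/division/division-period scores plus factor indices).
#' Use [write_reports()] to emit the report tables.
#'
#' @param data A [dea_panel()] or long data frame with the two-stage
#'   variable names (see [two_stage_spec()]).
#' @param carryover_division See [two_stage_spec()].
#' @param ... Passed to [dndea()] (`link_continuity`, `reoptimize`, ...).
#' @return A fitted `dndea` object.
#' @export
run_two_stage <- function(data, carryover_division = 1, ...) {
  spec <- two_stage_spec(carryover_division = carryover_division)
  dndea(data, spec, ...)
}
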