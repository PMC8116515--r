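# Policy scenario presets and end-to-end runs: the published what-if
# experiments (no intervention plus five programme parameterisations),
# activated in 2020 and simulated 1990-2035.

#' Scenario definition
#'
#' @param name Scenario label.
#' @param programs List of [program_spec()] objects (empty = no
#'   intervention). Programme names must be unique.
#' @param overrides Named list of journey-parameter overrides applied before
#'   the run, keyed by dotted parameter path (e.g.
#'   `"transitions.t2dm_recovery.fraction"`).
#' @return Object of class `scenario`.
#' @export
scenario <- function(name, programs = list(), overrides = list()) {
  nms <- vapply(programs, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("scenario: programme names must be unique")
  for (p in programs) validate_program_spec(p)
  structure(list(name = name, programs = programs, overrides = overrides),
            class = "scenario")
}

#' Names of the built-in scenario presets
#' @return Character vector of preset names accepted by [load_preset()].
#' @export
preset_names <- function() {
  c("no_intervention", "policy1_bariatric", "policy2_reversediabetes2now",
    "policy3", "policy4", "policy5")
}

#' Load a built-in policy preset
#'
#' Returns the published scenario parameterisations exactly as tabulated:
#' `no_intervention` (no programmes); `policy1_bariatric` (T2DM programme,
#' recruited 0.28, success 0.95, cost multiplier 17, bariatric relapse
#' 0.05 over 10 years); `policy2_reversediabetes2now` (T2DM programme,
#' recruited 0.002 ramping to 0.30 over 10 years, success 0.28, multiplier
#' 1); `policy3` (T2DM 0.3/0.3/1.0); `policy4` (T2DM 0.45/0.3/2.0 plus
#' pre-diabetes 0.3/0.3/1.0); `policy5` (T2DM 0.6/0.5/3.0 plus pre-diabetes
#' 0.4/0.5/3.0). All activate in January 2020. The narrative variants
#' `policy4_narrative` (T2DM success 0.45) and `policy5_narrative`
#' (multiplier 4, success 0.6) are also available where the running text
#' and the table disagree; the table is authoritative for the plain names.
#'
#' @param name Preset name; see [preset_names()].
#' @return A [scenario()].
#' @export
load_preset <- function(name) {
  presets <- list(
    no_intervention = scenario("no_intervention"),
    policy1_bariatric = scenario(
      "policy1_bariatric",
      list(program_spec("bariatric_surgery", target = "bariatric",
                        fraction_recruited = 0.28, success_rate = 0.95,
                        cost_multiplier = 17))),
    policy2_reversediabetes2now = scenario(
      "policy2_reversediabetes2now",
      list(program_spec("reversediabetes2now", target = "t2dm",
                        fraction_recruited = 0.002,
                        fraction_recruited_final = 0.30, ramp_years = 10,
                        success_rate = 0.28, cost_multiplier = 1))),
    policy3 = scenario(
      "policy3",
      list(program_spec("t2dm_program", target = "t2dm",
                        fraction_recruited = 0.3, success_rate = 0.3,
                        cost_multiplier = 1.0))),
    policy4 = scenario(
      "policy4",
      list(program_spec("t2dm_program", target = "t2dm",
                        fraction_recruited = 0.45, success_rate = 0.3,
                        cost_multiplier = 2.0),
           program_spec("prediabetes_program", target = "prediabetes",
                        fraction_recruited = 0.3, success_rate = 0.3,
                        cost_multiplier = 1.0))),
    policy5 = scenario(
      "policy5",
      list(program_spec("t2dm_program", target = "t2dm",
                        fraction_recruited = 0.6, success_rate = 0.5,
                        cost_multiplier = 3.0),
           program_spec("prediabetes_program", target = "prediabetes",
                        fraction_recruited = 0.4, success_rate = 0.5,
                        cost_multiplier = 3.0))),
    policy4_narrative = scenario(
      "policy4_narrative",
      list(program_spec("t2dm_program", target = "t2dm",
                        fraction_recruited = 0.45, success_rate = 0.45,
                        cost_multiplier = 2.0),
           program_spec("prediabetes_program", target = "prediabetes",
                        fraction_recruited = 0.3, success_rate = 0.3,
                        cost_multiplier = 1.0))),
    policy5_narrative = scenario(
      "policy5_narrative",
      list(program_spec("t2dm_program", target = "t2dm",
                        fraction_recruited = 0.6, success_rate = 0.6,
                        cost_multiplier = 4.0),
           program_spec("prediabetes_program", target = "prediabetes",
                        fraction_recruited = 0.4, success_rate = 0.5,
                        cost_multiplier = 3.0)))
  )
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  presets[[name]]
}

#' Run one policy scenario end to end
#'
#' Builds the journey system under the scenario's programmes and parameter
#' overrides, integrates it over the clock, and derives yearly outputs at
#' the 1-January census of each calendar year: the five stocks, the implied
#' total-DM estimate (T2DM / 0.9) and prevalence fraction, cumulative
#' deaths/recoveries/demographic inflow, the annual cost breakdown and its
#' running total. Deterministic: identical inputs give identical results.
#'
#' @param scen A [scenario()] or preset name.
#' @param params A [journey_parameters()] object.
#' @param cost_params A [cost_parameters()] object.
#' @param clock A [sim_clock()].
#' @return Object of class `scenario_result`: list with `name`,
#'   `trajectory` (monthly [sd_integrate()] output), `yearly` (data frame),
#'   `costs` (annual cost series), `clamp_events`, `clock`.
#' @export
run_scenario <- function(scen, params = journey_parameters(),
                         cost_params = cost_parameters(),
                         clock = sim_clock()) {
  if (is.character(scen)) scen <- load_preset(scen)
  if (!inherits(scen, "scenario")) stop("run_scenario: scen must be a scenario")
  for (path in names(scen$overrides))
    params <- param_set(params, path, scen$overrides[[path]])
  validate_journey_parameters(params)

  system <- journey_system(params, scen$programs, clock)
  traj <- sd_integrate(system, clock)
  acct <- journey_accounting(traj, system)

  years <- clock$start_year:clock$end_year
  idx <- match(clock_month(clock, years), traj$times)
  yearly <- data.frame(year = years,
                       traj$stocks[idx, JOURNEY_STOCKS, drop = FALSE])
  yearly$dm_estimate <- yearly$t2dm / params$t2dm_fraction_of_dm
  trend <- series_at(params$population_trend, years)
  yearly$t2dm_fraction <- ifelse(trend > 0, yearly$t2dm / trend, 0)
  yearly$cumulative_deaths <- acct$cumulative_deaths[idx]
  yearly$cumulative_recoveries <- acct$cumulative_recoveries[idx]
  yearly$cumulative_inflow <- acct$cumulative_inflow[idx]

  costs <- annual_cost_series(yearly, cost_params, scen$programs)
  yearly$total_cost <- costs$total
  yearly$cumulative_cost <- cumulative_cost(costs)

  structure(list(name = scen$name, scenario = scen, params = params,
                 cost_params = cost_params, clock = clock,
                 trajectory = traj, yearly = yearly, costs = costs,
                 clamp_events = traj$clamp_events),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  last <- x$yearly[nrow(x$yearly), ]
  cat(sprintf("<scenario_result> '%s' %d..%d\n", x$name,
              x$clock$start_year, x$clock$end_year))
  cat(sprintf("  T2DM %d: %s persons; total cost: %.2f B EUR/yr\n",
              last$year, format(round(last$t2dm), big.mark = ","),
              last$total_cost / 1e9))
  if (nrow(x$clamp_events))
    cat(sprintf("  %d clamp event(s)\n", nrow(x$clamp_events)))
  invisible(x)
}

#' Compare scenario runs against a reference
#'
#' The first result is the reference; for every result and report year the
#' table lists the T2DM stock, annual total cost and cumulative cost, plus
#' their differences from the reference (positive = more than the
#' reference). Differences are antisymmetric under swapping reference and
#' comparator.
#'
#' @param results List of [run_scenario()] results sharing one clock.
#' @param report_years Calendar years to tabulate.
#' @return Data frame, one row per (scenario, year).
#' @export
compare_scenarios <- function(results,
                              report_years = c(2020, 2025, 2030, 2035)) {
  if (!length(results)) stop("compare_scenarios: no results supplied")
  clocks <- lapply(results, function(r) unclass(r$clock)[c("start_year", "end_year", "dt")])
  if (length(unique(clocks)) != 1)
    stop("compare_scenarios: results must share one simulation clock")
  ref <- results[[1]]$yearly
  rows <- lapply(results, function(r) {
    i <- match(report_years, r$yearly$year)
    if (anyNA(i)) stop("compare_scenarios: report year outside the horizon")
    j <- match(report_years, ref$year)
    data.frame(scenario = r$name, year = report_years,
               t2dm = r$yearly$t2dm[i],
               total_cost = r$yearly$total_cost[i],
               cumulative_cost = r$yearly$cumulative_cost[i],
               t2dm_diff = r$yearly$t2dm[i] - ref$t2dm[j],
               cost_diff = r$yearly$total_cost[i] - ref$total_cost[j],
               cumulative_cost_diff =
                 r$yearly$cumulative_cost[i] - ref$cumulative_cost[j])
  })
  do.call(rbind, rows)
}
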