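# YAML run configuration: a single structured file holding the clock, the
# journey and cost parameter blocks, programme definitions and output
# options, with provenance tags for every placeholder value.

#' Default run configuration
#'
#' Emits the complete default configuration as a nested list (serialisable
#' to YAML with [write_config()]): clock, journey parameters including the
#' full transition table and population trend, cost parameters, programmes
#' (none) and output options. A `provenance` block tags each parameter
#' group as `paper` (printed source value), `trivial` (structural), or
#' `calibrated-placeholder` (value not publicly available, calibrated as
#' described in the methods vignette).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  jp <- journey_parameters()
  cp <- cost_parameters()
  trend <- jp$population_trend
  list(
    clock = list(start_year = 1990, end_year = 2035, dt_months = 1),
    journey = list(
      transitions = jp$transitions,
      ifg_fraction = jp$ifg_fraction,
      igt_fraction = jp$igt_fraction,
      healthy_life_expectancy = jp$healthy_life_expectancy,
      lifespan_shortening = as.list(jp$lifespan_shortening),
      t2dm_fraction_of_dm = jp$t2dm_fraction_of_dm,
      initial_dm_count = jp$initial_dm_count,
      fraction_developing_prediabetes = jp$fraction_developing_prediabetes,
      overweight_fraction = jp$overweight_fraction,
      obese_fraction = jp$obese_fraction,
      initial_prediabetes = jp$initial_prediabetes,
      population_trend = list(year = trend$year,
                              population = trend$population)),
    costs = unclass(cp),
    programs = list(),
    output = list(report_years = c(2020, 2025, 2030, 2035)),
    provenance = list(
      transitions = "paper",
      lifespan = "paper",
      overweight_obese_fractions = "paper",
      t2dm_fraction_of_dm = "paper",
      initial_dm_count = "paper",
      ifg_igt_fractions = "calibrated-placeholder",
      fraction_developing_prediabetes = "calibrated-placeholder",
      population_trend = "paper-implied-anchors",
      unit_costs = "calibrated-placeholder",
      base_program_cost = "calibrated-placeholder",
      initial_prediabetes = "trivial"))
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config Configuration list (see [default_config()]).
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config, precision = 15), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks the configuration by constructing the typed objects from it; any
#' violated invariant surfaces as an error naming the offending field.
#'
#' @param config Configuration list.
#' @return Invisibly, the list of constructed inputs (as
#'   [inputs_from_config()]).
#' @export
validate_config <- function(config) {
  invisible(inputs_from_config(config))
}

#' Construct simulation inputs from a configuration
#'
#' @param config Configuration list (see [default_config()]).
#' @return List with `clock`, `params`, `cost_params`, `scenario`,
#'   `report_years`.
#' @export
inputs_from_config <- function(config) {
  for (block in c("clock", "journey", "costs"))
    if (is.null(config[[block]]))
      stop(sprintf("configuration: missing '%s' block", block))
  cl <- config$clock
  clock <- sim_clock(cl$start_year, cl$end_year,
                     if (is.null(cl$dt_months)) 1 else cl$dt_months)
  j <- config$journey
  trend <- if (is.list(j$population_trend))
    data.frame(year = unlist(j$population_trend$year),
               population = unlist(j$population_trend$population))
  else j$population_trend
  init_pd <- j$initial_prediabetes
  if (is.list(init_pd)) init_pd <- unlist(init_pd)
  params <- journey_parameters(
    transitions = j$transitions,
    ifg_fraction = j$ifg_fraction,
    igt_fraction = j$igt_fraction,
    healthy_life_expectancy = j$healthy_life_expectancy,
    lifespan_shortening = unlist(j$lifespan_shortening),
    t2dm_fraction_of_dm = j$t2dm_fraction_of_dm,
    initial_dm_count = j$initial_dm_count,
    initial_t2dm_fraction = j$initial_t2dm_fraction,
    fraction_developing_prediabetes = j$fraction_developing_prediabetes,
    population_trend = trend,
    overweight_fraction = j$overweight_fraction,
    obese_fraction = j$obese_fraction,
    initial_prediabetes = init_pd)
  co <- config$costs
  co$bariatric_unit_cost_range <- unlist(co$bariatric_unit_cost_range)
  cost_params <- do.call(cost_parameters, co)
  programs <- lapply(config$programs, function(p) do.call(program_spec, p))
  scen <- scenario(if (is.null(config$name)) "configured_run" else config$name,
                   programs = programs)
  report_years <- if (!is.null(config$output$report_years))
    unlist(config$output$report_years) else c(2020, 2025, 2030, 2035)
  list(clock = clock, params = params, cost_params = cost_params,
       scenario = scen, report_years = report_years)
}
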