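# Model validation procedures: extreme-condition tests, one-at-a-time
# behaviour sensitivity analysis, and behaviour reproduction against
# national statistics reference anchors. All checks are pure reporting —
# they never mutate the configuration they are given.

#' Reference anchors for behaviour reproduction
#'
#' Text-reported national statistics points: total diabetes patient counts
#' (1990: 160,000; 2011: 830,000; 2018: 1.2 million) and T2DM shares of the
#' population (2014: 3.7%; 2019: 4.0%).
#'
#' @return Data frame with columns `year`, `kind` (`"dm_count"` or
#'   `"t2dm_fraction"`) and `value`.
#' @export
reference_anchors <- function() {
  data.frame(
    year = c(1990, 2011, 2018, 2014, 2019),
    kind = c("dm_count", "dm_count", "dm_count",
             "t2dm_fraction", "t2dm_fraction"),
    value = c(160000, 830000, 1200000, 0.037, 0.040))
}

#' Behaviour reproduction against reference anchors
#'
#' Compares a simulated run against the anchors: diabetes-count anchors are
#' matched to the simulated T2DM stock divided by the 0.9 type 2 share (the
#' anchors count all diabetes), fraction anchors to the simulated T2DM
#' prevalence. Reports the relative error per anchor, the mean absolute
#' percentage error, and a pass flag per anchor at the given tolerance.
#'
#' @param result A [run_scenario()] result.
#' @param anchors Data frame as [reference_anchors()].
#' @param tolerance Relative-error threshold for the per-anchor pass flag
#'   (default 0.2).
#' @return Data frame with per-anchor `simulated`, `rel_error` and `pass`;
#'   attributes `mape` (mean absolute percentage error, percent) and
#'   `pass` (all anchors within tolerance).
#' @export
behavior_reproduction <- function(result, anchors = reference_anchors(),
                                  tolerance = 0.2) {
  yearly <- result$yearly
  if (any(!anchors$year %in% yearly$year))
    stop("behavior_reproduction: anchor year outside the simulation horizon")
  i <- match(anchors$year, yearly$year)
  simulated <- ifelse(anchors$kind == "dm_count",
                      yearly$dm_estimate[i],
                      yearly$t2dm_fraction[i])
  rel_error <- (simulated - anchors$value) / anchors$value
  out <- cbind(anchors,
               data.frame(simulated = simulated, rel_error = rel_error,
                          pass = abs(rel_error) <= tolerance))
  attr(out, "mape") <- mean(abs(rel_error)) * 100
  attr(out, "pass") <- all(out$pass)
  out
}

#' Extreme-condition test
#'
#' Runs the documented extremes and checks the model still behaves
#' rationally: (a) an emptied system (all stocks and the population trend at
#' zero) must produce zero T2DM-attributable cost at every year, stay at
#' zero and never go negative; (b) a 100-million-patient T2DM population
#' must remain finite, never negative, cost billions of euros under the
#' default unit costs, and scale costs proportionally with the stock.
#'
#' @param params A [journey_parameters()] object (used as the base; the
#'   extremes override its initial stocks and trend).
#' @param cost_params A [cost_parameters()] object.
#' @param clock A [sim_clock()].
#' @return Data frame of assertion outcomes (`check`, `passed`, `detail`);
#'   attribute `pass` summarises all rows.
#' @export
extreme_condition_test <- function(params = journey_parameters(),
                                   cost_params = cost_parameters(),
                                   clock = sim_clock()) {
  checks <- list()
  note <- function(check, passed, detail)
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, passed = passed, detail = detail)

  # (a) empty system
  p0 <- params
  p0$population_trend <- 0
  p0$initial_dm_count <- 0
  p0$initial_prediabetes <- "zero"
  r0 <- run_scenario(scenario("extreme_zero"), p0, cost_params, clock)
  note("zero population: zero cost at every year",
       all(r0$yearly$total_cost == 0),
       sprintf("max |cost| = %g EUR", max(abs(r0$yearly$total_cost))))
  note("zero population: stocks stay at zero",
       all(r0$trajectory$stocks == 0),
       sprintf("max stock = %g", max(r0$trajectory$stocks)))

  # (b) 100 million T2DM patients
  p1 <- params
  p1$population_trend <- 120e6
  p1$initial_dm_count <- 100e6 / params$t2dm_fraction_of_dm
  r1 <- run_scenario(scenario("extreme_large"), p1, cost_params, clock)
  note("100M extreme: all stocks finite",
       all(is.finite(r1$trajectory$stocks)), "no overflow/NaN")
  note("100M extreme: no negative stocks",
       min(r1$trajectory$stocks) >= 0,
       sprintf("min stock = %g", min(r1$trajectory$stocks)))
  note("100M extreme: costs in the billions",
       r1$yearly$total_cost[1] > 1e9,
       sprintf("initial-year cost = %.1f B EUR", r1$yearly$total_cost[1] / 1e9))
  state_1m <- c(normoglycemic = 0, undiagnosed_prediabetic = 0,
                diagnosed_prediabetic = 0, t2dm = 1e6,
                no_medicine_necessary = 0)
  state_100m <- state_1m; state_100m["t2dm"] <- 100e6
  ratio <- annual_cost(state_100m, cost_params)$total /
    annual_cost(state_1m, cost_params)$total
  note("100M extreme: cost scales proportionally with the T2DM stock",
       abs(ratio - 100) < 1e-9, sprintf("100x stock -> %.6fx cost", ratio))

  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$passed)
  out
}

#' One-at-a-time behaviour sensitivity analysis
#'
#' Perturbs each named parameter by a relative amount in both directions,
#' reruns the scenario, and reports per-stock elasticities
#' `(dOutput/Output) / (dParam/Param)` at the output year. Deterministic and
#' reproducible bit for bit.
#'
#' @param parameters Character vector of dotted parameter paths into
#'   [journey_parameters()] (e.g. `"transitions.onset_overweight.fraction"`,
#'   `"ifg_fraction"`, `"fraction_developing_prediabetes"`,
#'   `"overweight_fraction"`).
#' @param perturbation Relative perturbation (> 0), default 0.1 (i.e. ±10%).
#' @param params,cost_params,clock Model configuration.
#' @param scen Scenario to perturb (default: no intervention).
#' @param output_year Year at which outputs are compared.
#' @return Data frame: `parameter`, `direction` (+1/-1), `stock`,
#'   `baseline`, `perturbed`, `elasticity`.
#' @export
sensitivity_analysis <- function(parameters, perturbation = 0.1,
                                 params = journey_parameters(),
                                 cost_params = cost_parameters(),
                                 clock = sim_clock(),
                                 scen = load_preset("no_intervention"),
                                 output_year = 2035) {
  if (perturbation <= 0) stop("sensitivity_analysis: perturbation must be > 0")
  run_stocks <- function(p) {
    r <- run_scenario(scen, p, cost_params, clock)
    i <- match(output_year, r$yearly$year)
    if (is.na(i)) stop("sensitivity_analysis: output_year outside the horizon")
    unlist(r$yearly[i, JOURNEY_STOCKS])
  }
  base <- run_stocks(params)
  rows <- list()
  for (path in parameters) {
    p0 <- param_get(params, path)  # errors on unknown parameter names
    if (!is.numeric(p0) || length(p0) != 1)
      stop(sprintf("sensitivity_analysis: parameter '%s' is not a scalar", path))
    for (dir in c(1, -1)) {
      pp <- param_set(params, path, p0 * (1 + dir * perturbation))
      pert <- run_stocks(pp)
      rel_out <- ifelse(base > 0, (pert - base) / base, 0)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = path, direction = dir, stock = names(base),
        baseline = unname(base), perturbed = unname(pert),
        elasticity = unname(rel_out / (dir * perturbation)),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
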