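# The patient-journey stock structure: normoglycemic -> (un)diagnosed
# pre-diabetes -> T2DM, with recovery, reversal and relapse paths, per-stock
# mortality and demographic replenishment of the normoglycemic stock.

JOURNEY_STOCKS <- c("normoglycemic", "undiagnosed_prediabetic",
                    "diagnosed_prediabetic", "t2dm", "no_medicine_necessary")

#' First-order transition rate between stocks
#'
#' The share `fraction` of a stock makes a transition over an average time
#' `avg_time` (years), giving a flow of
#' `stock_value * fraction / (avg_time * 12)` persons per month.
#'
#' @param stock_value Source stock size (persons), non-negative.
#' @param fraction Dimensionless fraction in \[0, 1\].
#' @param avg_time Average transition time in years (> 0).
#' @return Flow rate in persons per month.
#' @examples
#' transition_rate(1200, 0.70, 4)  # 17.5 persons/month
#' @export
transition_rate <- function(stock_value, fraction, avg_time) {
  if (any(avg_time <= 0)) stop("transition_rate: avg_time must be > 0")
  if (any(fraction < 0 | fraction > 1))
    stop("transition_rate: fraction must lie in [0, 1]")
  if (any(stock_value < 0))
    stop("transition_rate: stock_value must be non-negative")
  stock_value * fraction / (avg_time * 12)
}

#' Pre-diabetes onset flow from the normoglycemic stock
#'
#' Splits the normoglycemic stock into overweight and non-overweight
#' compartments by the exogenous overweight fraction, applies each
#' compartment's `(fraction, avg_time)` onset pair, and returns the summed
#' rate of persons becoming pre-diabetic. The result is the raw transition-
#' table rate; the journey derivatives additionally scale it by
#' `fraction_developing_prediabetes` (see [journey_parameters()]).
#'
#' @param normoglycemic Normoglycemic stock (persons).
#' @param overweight_fraction Share of the stock that is overweight, in
#'   \[0, 1\].
#' @param params A [journey_parameters()] object (onset rows of the
#'   transition table are used).
#' @return Onset rate in persons per month.
#' @examples
#' p <- journey_parameters()
#' prediabetes_onset(1e6, 0.51, p)  # 204.2 + 4675.0 persons/month
#' @export
prediabetes_onset <- function(normoglycemic, overweight_fraction, params) {
  if (overweight_fraction < 0 || overweight_fraction > 1)
    stop("prediabetes_onset: overweight_fraction must lie in [0, 1]")
  non_ow <- params$transitions$onset_nonoverweight
  ow <- params$transitions$onset_overweight
  transition_rate(normoglycemic * (1 - overweight_fraction),
                  non_ow$fraction, non_ow$avg_time) +
    transition_rate(normoglycemic * overweight_fraction,
                    ow$fraction, ow$avg_time)
}

#' Split the onset flow into diagnosed and undiagnosed inflows
#'
#' The IFG and IGT incidence fractions together give the share of new
#' pre-diabetics who receive a diagnosis; the remainder stay undiagnosed.
#' The two outputs sum to the onset rate exactly.
#'
#' @param onset_rate Total pre-diabetes onset (persons per month).
#' @param ifg_fraction,igt_fraction Diagnosis incidence fractions;
#'   `ifg_fraction + igt_fraction` must not exceed 1.
#' @return Named numeric `c(diagnosed = , undiagnosed = )`.
#' @examples
#' diagnosis_split(100, 0.2, 0.1)  # 30 diagnosed, 70 undiagnosed
#' @export
diagnosis_split <- function(onset_rate, ifg_fraction, igt_fraction) {
  d <- ifg_fraction + igt_fraction
  if (d > 1) stop("diagnosis_split: ifg_fraction + igt_fraction exceeds 1")
  if (d < 0) stop("diagnosis_split: fractions must be non-negative")
  c(diagnosed = onset_rate * d, undiagnosed = onset_rate * (1 - d))
}

#' Mortality outflow of a stock
#'
#' Per-capita outflow at rate one over the remaining life expectancy: an
#' exponential residence-time approximation of "leaving when reaching the
#' average life expectancy" of that health state.
#'
#' @param stock_value Stock size (persons).
#' @param remaining_life Remaining life expectancy in years (> 0; `Inf`
#'   disables mortality).
#' @return Death rate in persons per month.
#' @examples
#' death_rate(872400, 81.7 - 9)  # T2DM stock, 1000 persons/month
#' @export
death_rate <- function(stock_value, remaining_life) {
  if (any(remaining_life <= 0)) stop("death_rate: remaining_life must be > 0")
  stock_value / (remaining_life * 12)
}

# Relapse parameters governing the shared no-medicine stock: taken from the
# active T2DM-targeted programme (bariatric surgery has its own pair);
# lifestyle default when no programme is active (the stock is then empty).
resolve_relapse <- function(params, programs) {
  t2dm_prog <- Filter(function(p) p$active && p$target %in% c("t2dm", "bariatric"),
                      programs)
  if (!length(t2dm_prog)) {
    tr <- params$transitions$relapse_lifestyle
    return(list(fraction = tr$fraction, time = tr$avg_time))
  }
  pairs <- unique(lapply(t2dm_prog, function(p)
    c(p$relapse_fraction, p$relapse_time)))
  if (length(pairs) > 1)
    stop("journey model: active T2DM-targeted programmes disagree on relapse parameters")
  list(fraction = pairs[[1]][1], time = pairs[[1]][2])
}

#' Evaluate all journey flow rates at a state
#'
#' Emits every flow of the patient-journey structure as a named vector of
#' rates in persons per month: the split pre-diabetes onset, progression to
#' T2DM, recoveries, programme recruitment/reversal, relapse and sustained
#' recovery out of the no-medicine stock, per-stock deaths, and the
#' demographic replenishment that keeps the total population on the
#' exogenous trend.
#'
#' @param state Named numeric vector containing at least the five journey
#'   stocks.
#' @param params A [journey_parameters()] object.
#' @param programs List of [program_spec()] objects (programme flows are
#'   zero when empty or before activation).
#' @param t Time in months since January of `start_year`.
#' @param dt Step size in months (used by the replenishment flow).
#' @param start_year Calendar year at t = 0.
#' @return Named numeric vector of flow rates.
#' @export
journey_derivatives <- function(state, params, programs = list(), t = 0,
                                dt = 1, start_year = 1990) {
  year <- start_year + t / 12
  tr <- params$transitions
  ow <- series_at(params$overweight_fraction, year)
  onset <- prediabetes_onset(state[["normoglycemic"]], ow, params) *
    params$fraction_developing_prediabetes
  split <- diagnosis_split(onset, params$ifg_fraction, params$igt_fraction)
  relapse_pars <- resolve_relapse(params, programs)
  nm <- state[["no_medicine_necessary"]]

  rates <- c(
    onset_diagnosed = unname(split["diagnosed"]),
    onset_undiagnosed = unname(split["undiagnosed"]),
    diagnosed_to_t2dm = transition_rate(state[["diagnosed_prediabetic"]],
                                        tr$diagnosed_to_t2dm$fraction,
                                        tr$diagnosed_to_t2dm$avg_time),
    undiagnosed_to_t2dm = transition_rate(state[["undiagnosed_prediabetic"]],
                                          tr$undiagnosed_to_t2dm$fraction,
                                          tr$undiagnosed_to_t2dm$avg_time),
    diagnosed_recovery = transition_rate(state[["diagnosed_prediabetic"]],
                                         tr$diagnosed_recovery$fraction,
                                         tr$diagnosed_recovery$avg_time),
    undiagnosed_recovery = transition_rate(state[["undiagnosed_prediabetic"]],
                                           tr$undiagnosed_recovery$fraction,
                                           tr$undiagnosed_recovery$avg_time),
    t2dm_recovery = transition_rate(state[["t2dm"]],
                                    tr$t2dm_recovery$fraction,
                                    tr$t2dm_recovery$avg_time),
    relapse = nm * relapse_pars$fraction / (relapse_pars$time * 12),
    sustained_recovery = nm * (1 - relapse_pars$fraction) /
      (relapse_pars$time * 12),
    deaths_normoglycemic = death_rate(state[["normoglycemic"]],
                                      remaining_life(params, "normoglycemic")),
    deaths_undiagnosed = death_rate(state[["undiagnosed_prediabetic"]],
                                    remaining_life(params, "undiagnosed_prediabetic")),
    deaths_diagnosed = death_rate(state[["diagnosed_prediabetic"]],
                                  remaining_life(params, "diagnosed_prediabetic")),
    deaths_t2dm = death_rate(state[["t2dm"]],
                             remaining_life(params, "t2dm")),
    deaths_no_medicine = death_rate(nm,
                                    remaining_life(params, "no_medicine_necessary"))
  )

  for (prog in programs) {
    eligible <- if (prog$target == "prediabetes")
      state[["diagnosed_prediabetic"]] else state[["t2dm"]]
    recruited <- recruitment_rate(eligible, prog, year)
    rates[paste0("program_", prog$name)] <-
      program_recovery_flow(recruited, prog$success_rate)
  }

  total <- sum(state[JOURNEY_STOCKS])
  trend_next <- series_at(params$population_trend, year + dt / 12)
  rates["replenishment"] <- (trend_next - total) / dt +
    sum(rates[c("deaths_normoglycemic", "deaths_undiagnosed",
                "deaths_diagnosed", "deaths_t2dm", "deaths_no_medicine")])
  rates
}

#' Initial journey state
#'
#' Seeds the T2DM stock from the prevalence anchor (default: the 1990 count
#' of 160,000 DM patients times the 0.9 T2DM share), the two pre-diabetic
#' stocks per `params$initial_prediabetes`, and assigns the remainder of the
#' population trend at the start year to the normoglycemic stock, so the
#' five stocks sum exactly to the trend.
#'
#' @param params A [journey_parameters()] object.
#' @param clock A [sim_clock()]; only `start_year` is used.
#' @return Named numeric vector: the five journey stocks plus zero-valued
#'   `cumulative_deaths`, `cumulative_recoveries`, `cumulative_inflow`
#'   accounting fields.
#' @export
initialize_state <- function(params, clock = sim_clock()) {
  trend0 <- series_at(params$population_trend, clock$start_year)
  t2dm0 <- if (!is.null(params$initial_t2dm_fraction))
    trend0 * params$initial_t2dm_fraction
  else
    params$initial_dm_count * params$t2dm_fraction_of_dm
  if (t2dm0 > trend0)
    stop("initialize_state: initial T2DM stock exceeds the population trend")

  avail <- trend0 - t2dm0
  init_pd <- params$initial_prediabetes
  if (identical(init_pd, "zero")) {
    diag0 <- 0; undiag0 <- 0; normo0 <- avail
  } else if (is.numeric(init_pd)) {
    diag0 <- unname(init_pd["diagnosed"])
    undiag0 <- unname(init_pd["undiagnosed"])
    normo0 <- avail - diag0 - undiag0
  } else if (identical(init_pd, "steady_state")) {
    # Pre-diabetic stocks consistent with the initial onset flow: solve the
    # linear fixed point diag = a*normo, undiag = b*normo,
    # normo = avail / (1 + a + b), where a and b balance each stock's
    # inflow against its total outflow rate.
    tr <- params$transitions
    ow <- series_at(params$overweight_fraction, clock$start_year)
    onset_per_normo <- prediabetes_onset(1, ow, params) *
      params$fraction_developing_prediabetes
    d_share <- params$ifg_fraction + params$igt_fraction
    out_diag <- tr$diagnosed_to_t2dm$fraction / (tr$diagnosed_to_t2dm$avg_time * 12) +
      tr$diagnosed_recovery$fraction / (tr$diagnosed_recovery$avg_time * 12) +
      1 / (remaining_life(params, "diagnosed_prediabetic") * 12)
    out_undiag <- tr$undiagnosed_to_t2dm$fraction / (tr$undiagnosed_to_t2dm$avg_time * 12) +
      tr$undiagnosed_recovery$fraction / (tr$undiagnosed_recovery$avg_time * 12) +
      1 / (remaining_life(params, "undiagnosed_prediabetic") * 12)
    a <- onset_per_normo * d_share / out_diag
    b <- onset_per_normo * (1 - d_share) / out_undiag
    normo0 <- avail / (1 + a + b)
    diag0 <- a * normo0
    undiag0 <- b * normo0
  } else {
    stop("initialize_state: initial_prediabetes must be \"steady_state\", \"zero\" or a named numeric")
  }
  if (normo0 < 0)
    stop("initialize_state: negative initial normoglycemic stock; check the anchor and pre-diabetic seeds")
  c(normoglycemic = normo0,
    undiagnosed_prediabetic = undiag0,
    diagnosed_prediabetic = diag0,
    t2dm = t2dm0,
    no_medicine_necessary = 0,
    cumulative_deaths = 0,
    cumulative_recoveries = 0,
    cumulative_inflow = 0)
}

#' Build the journey stock-flow system
#'
#' Assembles the five-stock patient-journey structure (plus programme flows
#' for the supplied programmes) as a [stock_flow_system()] ready for
#' [sd_integrate()].
#'
#' @param params A [journey_parameters()] object.
#' @param programs List of [program_spec()] objects.
#' @param clock A [sim_clock()].
#' @param initial Optional named state overriding [initialize_state()].
#' @return A `stock_flow_system`.
#' @export
journey_system <- function(params, programs = list(), clock = sim_clock(),
                           initial = NULL) {
  validate_journey_parameters(params)
  for (p in programs) validate_program_spec(p)
  state0 <- if (is.null(initial)) initialize_state(params, clock) else initial
  stocks <- state0[JOURNEY_STOCKS]

  topo <- list(
    flow("onset_diagnosed", from = "normoglycemic", to = "diagnosed_prediabetic"),
    flow("onset_undiagnosed", from = "normoglycemic", to = "undiagnosed_prediabetic"),
    flow("diagnosed_to_t2dm", from = "diagnosed_prediabetic", to = "t2dm"),
    flow("undiagnosed_to_t2dm", from = "undiagnosed_prediabetic", to = "t2dm"),
    flow("diagnosed_recovery", from = "diagnosed_prediabetic", to = "normoglycemic"),
    flow("undiagnosed_recovery", from = "undiagnosed_prediabetic", to = "normoglycemic"),
    flow("t2dm_recovery", from = "t2dm", to = "normoglycemic"),
    flow("relapse", from = "no_medicine_necessary", to = "t2dm"),
    flow("sustained_recovery", from = "no_medicine_necessary", to = "normoglycemic"),
    flow("deaths_normoglycemic", from = "normoglycemic"),
    flow("deaths_undiagnosed", from = "undiagnosed_prediabetic"),
    flow("deaths_diagnosed", from = "diagnosed_prediabetic"),
    flow("deaths_t2dm", from = "t2dm"),
    flow("deaths_no_medicine", from = "no_medicine_necessary"),
    flow("replenishment", to = "normoglycemic")
  )
  for (prog in programs) {
    topo <- c(topo, list(
      if (prog$target == "prediabetes")
        flow(paste0("program_", prog$name),
             from = "diagnosed_prediabetic", to = "normoglycemic")
      else
        flow(paste0("program_", prog$name),
             from = "t2dm", to = "no_medicine_necessary")))
  }

  stock_flow_system(
    stocks = stocks,
    flows = topo,
    rate_fn = function(state, t, dt)
      journey_derivatives(state, params, programs, t, dt,
                          start_year = clock$start_year))
}

# Cumulative accounting derived exactly from the realised Euler flow rates:
# deaths leave through the cloud, demographic replenishment enters from it,
# and recoveries are every inter-stock flow whose sink is the normoglycemic
# stock (programme reversals into "no medicine necessary" are not yet
# sustained recoveries).
journey_accounting <- function(traj, system) {
  dt <- traj$clock$dt
  is_death <- vapply(system$flows, function(f) is.null(f$to), logical(1))
  is_inflow <- vapply(system$flows, function(f) is.null(f$from), logical(1))
  is_recovery <- vapply(system$flows, function(f)
    !is.null(f$from) && identical(f$to, "normoglycemic"), logical(1))
  csum <- function(sel) {
    if (!any(sel)) return(rep(0, nrow(traj$stocks)))
    c(0, cumsum(rowSums(traj$flows[, sel, drop = FALSE]) * dt))
  }
  data.frame(
    time = traj$times,
    cumulative_deaths = csum(is_death),
    cumulative_recoveries = csum(is_recovery),
    cumulative_inflow = csum(is_inflow))
}
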