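# Generic deterministic stock-and-flow machinery: a fixed-step forward-Euler
# integrator over named stocks connected by named flows. Higher layers build
# the patient-journey model on top of this.

#' Simulation clock
#'
#' Defines the simulated calendar horizon and the fixed integration step.
#' Time is measured internally in months since January of `start_year`
#' (t = 0). Yearly outputs are taken at the 1-January census instant of each
#' calendar year, so a `start_year = 1990`, `end_year = 2035` clock spans 540
#' monthly steps and reports 46 yearly values (1990..2035).
#'
#' @param start_year First simulated calendar year.
#' @param end_year Last simulated calendar year (its 1-January state is the
#'   final reported value).
#' @param dt Integration step in months. Must divide the horizon into an
#'   integer number of steps.
#' @return An object of class `sim_clock`.
#' @examples
#' clock <- sim_clock(1990, 2035)
#' clock$n_steps  # 540 monthly steps
#' @export
sim_clock <- function(start_year = 1990, end_year = 2035, dt = 1) {
  if (!is.numeric(start_year) || !is.numeric(end_year) || !is.numeric(dt))
    stop("sim_clock: start_year, end_year and dt must be numeric")
  if (end_year <= start_year)
    stop("sim_clock: end_year must be greater than start_year")
  if (dt <= 0)
    stop("sim_clock: dt must be positive")
  horizon <- (end_year - start_year) * 12
  n_steps <- horizon / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("sim_clock: (end_year - start_year) * 12 / dt must be an integer")
  n_steps <- as.integer(round(n_steps))
  structure(
    list(start_year = start_year, end_year = end_year, dt = dt,
         n_steps = n_steps, times = seq(0, horizon, by = dt)),
    class = "sim_clock")
}

#' @export
print.sim_clock <- function(x, ...) {
  cat(sprintf("<sim_clock> %d..%d, dt = %g month(s), %d steps\n",
              x$start_year, x$end_year, x$dt, x$n_steps))
  invisible(x)
}

#' Month index of the 1-January census of a calendar year
#' @param clock A [sim_clock()].
#' @param year Calendar year(s) within the clock horizon.
#' @return Time in months since the clock origin.
#' @export
clock_month <- function(clock, year) {
  if (any(year < clock$start_year | year > clock$end_year))
    stop("clock_month: year outside the simulation horizon")
  (year - clock$start_year) * 12
}

#' Declare a flow between two stocks
#'
#' A flow moves quantity from a source stock to a sink stock at a rate given
#' by `rate(stocks, t, dt)` (units: stock units per month). Either end may be
#' `NULL`, the external "cloud": a `NULL` source is an inflow from outside the
#' system, a `NULL` sink an outflow leaving it.
#'
#' @param name Flow name (unique within a system).
#' @param rate Function `(stocks, t, dt) -> numeric(1)` giving the rate per
#'   month, or `NULL` when the owning system supplies a joint `rate_fn`.
#' @param from,to Names of source/sink stocks, or `NULL` for the cloud.
#' @export
flow <- function(name, rate = NULL, from = NULL, to = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(rate) && !is.function(rate))
    stop("flow: rate must be a function or NULL")
  structure(list(name = name, rate = rate, from = from, to = to),
            class = "sd_flow")
}

#' Assemble a stock-and-flow system
#'
#' @param stocks Named numeric vector of initial stock values.
#' @param flows List of [flow()] objects. All `from`/`to` names must resolve
#'   to a declared stock.
#' @param auxiliaries Optional named list of exogenous constants/series kept
#'   with the system (not interpreted by the integrator).
#' @param rate_fn Optional function `(stocks, t, dt)` returning the named
#'   vector of all flow rates at once; when supplied, per-flow `rate`
#'   functions are ignored.
#' @param non_negative Logical vector (recycled) marking stocks clamped at
#'   zero after each step. Defaults to all `TRUE`.
#' @return An object of class `stock_flow_system`.
#' @export
stock_flow_system <- function(stocks, flows, auxiliaries = list(),
                              rate_fn = NULL, non_negative = TRUE) {
  if (is.null(names(stocks)) || any(!nzchar(names(stocks))))
    stop("stock_flow_system: stocks must be a named numeric vector")
  if (anyDuplicated(names(stocks)))
    stop("stock_flow_system: duplicate stock names")
  if (!all(is.finite(stocks)))
    stop("stock_flow_system: initial stock values must be finite")
  flow_names <- vapply(flows, function(f) f$name, character(1))
  if (anyDuplicated(flow_names))
    stop("stock_flow_system: duplicate flow names")
  for (f in flows) {
    if (!inherits(f, "sd_flow"))
      stop("stock_flow_system: flows must be built with flow()")
    for (end in c(f$from, f$to))
      if (!is.null(end) && !end %in% names(stocks))
        stop(sprintf("stock_flow_system: flow '%s' references unknown stock '%s'",
                     f$name, end))
    if (is.null(rate_fn) && !is.function(f$rate))
      stop(sprintf("stock_flow_system: flow '%s' has no rate function", f$name))
  }
  non_negative <- rep_len(as.logical(non_negative), length(stocks))
  names(non_negative) <- names(stocks)
  structure(
    list(stocks = stocks, flows = flows, flow_names = flow_names,
         auxiliaries = auxiliaries, rate_fn = rate_fn,
         non_negative = non_negative),
    class = "stock_flow_system")
}

#' One forward-Euler step
#'
#' Updates each stock by `dt` times its net flow (inflows minus outflows).
#' Stocks marked non-negative are clamped at zero afterwards; the clamped
#' amounts are returned so callers can log them.
#'
#' @param state Named numeric vector of current stock values.
#' @param flows List of [flow()] objects giving the source/sink topology.
#' @param rates Numeric vector of flow rates (per month) evaluated at
#'   `state`, aligned with `flows`.
#' @param dt Step size in months.
#' @param non_negative Logical vector aligned with `state`; clamp these
#'   stocks at zero.
#' @return List with `state` (updated stocks) and `clamped` (named vector of
#'   amounts removed by clamping; empty when none).
#' @export
euler_step <- function(state, flows, rates, dt,
                       non_negative = rep(TRUE, length(state))) {
  if (dt <= 0) stop("euler_step: dt must be positive")
  if (length(rates) != length(flows))
    stop("euler_step: rates must align with flows")
  bad <- !is.finite(rates)
  if (any(bad)) {
    nm <- vapply(flows[bad], function(f) f$name, character(1))
    stop(sprintf("euler_step: non-finite rate for flow(s): %s",
                 paste(nm, collapse = ", ")))
  }
  net <- numeric(length(state))
  names(net) <- names(state)
  for (i in seq_along(flows)) {
    f <- flows[[i]]
    if (!is.null(f$from)) net[f$from] <- net[f$from] - rates[i]
    if (!is.null(f$to))   net[f$to]   <- net[f$to]   + rates[i]
  }
  out <- state + dt * net
  clamped <- numeric(0)
  below <- non_negative & out < 0
  if (any(below)) {
    clamped <- -out[below]
    out[below] <- 0
  }
  list(state = out, clamped = clamped)
}

#' Integrate a stock-and-flow system over a clock
#'
#' Runs fixed-step forward Euler over the full horizon. The run is
#' deterministic: identical inputs give bit-identical trajectories. Negative
#' stocks are clamped at zero and each clamping event is logged in the
#' returned trajectory.
#'
#' @param system A [stock_flow_system()].
#' @param clock A [sim_clock()].
#' @return An object of class `sd_trajectory`: list with `times` (months),
#'   `stocks` (matrix, one row per time point), `flows` (matrix of realised
#'   rates, one row per step), `clamp_events` (data frame) and the `clock`.
#' @export
sd_integrate <- function(system, clock) {
  if (!inherits(system, "stock_flow_system"))
    stop("sd_integrate: system must be a stock_flow_system")
  if (!inherits(clock, "sim_clock"))
    stop("sd_integrate: clock must be a sim_clock")
  n <- clock$n_steps
  dt <- clock$dt
  state <- system$stocks
  stocks <- matrix(NA_real_, nrow = n + 1L, ncol = length(state),
                   dimnames = list(NULL, names(state)))
  flows_m <- matrix(NA_real_, nrow = n, ncol = length(system$flows),
                    dimnames = list(NULL, system$flow_names))
  stocks[1L, ] <- state
  clamp_time <- numeric(0); clamp_stock <- character(0); clamp_amount <- numeric(0)
  for (k in seq_len(n)) {
    t <- clock$times[k]
    if (!is.null(system$rate_fn)) {
      rates <- system$rate_fn(state, t, dt)
      rates <- rates[system$flow_names]
    } else {
      rates <- vapply(system$flows, function(f) f$rate(state, t, dt),
                      numeric(1))
    }
    step <- euler_step(state, system$flows, rates, dt, system$non_negative)
    state <- step$state
    stocks[k + 1L, ] <- state
    flows_m[k, ] <- rates
    if (length(step$clamped)) {
      clamp_time <- c(clamp_time, rep(t + dt, length(step$clamped)))
      clamp_stock <- c(clamp_stock, names(step$clamped))
      clamp_amount <- c(clamp_amount, unname(step$clamped))
    }
  }
  structure(
    list(times = clock$times, stocks = stocks, flows = flows_m,
         clamp_events = data.frame(time = clamp_time, stock = clamp_stock,
                                   amount = clamp_amount),
         clock = clock),
    class = "sd_trajectory")
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("<sd_trajectory> %d stocks x %d time points (%d..%d)\n",
              ncol(x$stocks), length(x$times),
              x$clock$start_year, x$clock$end_year))
  if (nrow(x$clamp_events))
    cat(sprintf("  %d clamp event(s) logged\n", nrow(x$clamp_events)))
  invisible(x)
}

#' @param row.names,optional Ignored (data frame method signature).
#' @param ... Unused.
#' @rdname sd_integrate
#' @export
as.data.frame.sd_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(time = x$times, year = x$clock$start_year + x$times / 12,
             x$stocks, check.names = FALSE)
}
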