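# Programmatically generated inputs: exogenous demographic series, small
# hand-checkable toy systems with closed-form solutions, and fixture files
# written from code (never bundled opaque data).

#' Exogenous demographic series
#'
#' Yearly values of the demographic drivers: total population (the default
#' trend of [population_trend_default()]), overweight fraction (0.51),
#' obese fraction (0.15) and elderly fraction (0.20), all constant
#' fractions by default. Year-on-year population changes stay below 5%.
#'
#' @param years Years covered (default 1990..2035).
#' @param overweight_fraction,obese_fraction,elderly_fraction Constants or
#'   vectors recycled over `years`.
#' @return Data frame, one row per year.
#' @export
demographic_series <- function(years = 1990:2035,
                               overweight_fraction = 0.51,
                               obese_fraction = 0.15,
                               elderly_fraction = 0.20) {
  trend <- population_trend_default(years)
  data.frame(year = years,
             population = trend$population,
             overweight_fraction = rep_len(overweight_fraction, length(years)),
             obese_fraction = rep_len(obese_fraction, length(years)),
             elderly_fraction = rep_len(elderly_fraction, length(years)))
}

#' Toy stock-flow systems with closed-form oracles
#'
#' Small systems whose exact solutions are known, used to verify the Euler
#' integrator:
#' \describe{
#'   \item{`decay`}{one stock draining at rate S/tau (tau = 24 months);
#'     solution `S0 * exp(-t / 24)`.}
#'   \item{`two_stock_transfer`}{A drains into B at rate A/tau (tau = 12
#'     months); A + B is conserved exactly.}
#'   \item{`logistic_population`}{the birth/death/carrying-capacity loops of
#'     a simple population model: births at 4%/yr, deaths at 4%/yr times
#'     P/K, giving logistic growth that levels off at the carrying capacity
#'     K without ever exceeding it.}
#' }
#'
#' @param name One of `"decay"`, `"two_stock_transfer"`,
#'   `"logistic_population"`.
#' @return List with `system` (a [stock_flow_system()]) and `solution`, a
#'   function of time in months returning the exact stock values.
#' @export
toy_system <- function(name = c("decay", "two_stock_transfer",
                                "logistic_population")) {
  name <- match.arg(name)
  switch(name,
    decay = {
      s0 <- 1000; tau <- 24
      list(
        system = stock_flow_system(
          stocks = c(S = s0),
          flows = list(flow("drain", function(s, t, dt) s[["S"]] / tau,
                            from = "S"))),
        solution = function(t) c(S = s0 * exp(-t / tau)))
    },
    two_stock_transfer = {
      a0 <- 1000; b0 <- 0; tau <- 12
      list(
        system = stock_flow_system(
          stocks = c(A = a0, B = b0),
          flows = list(flow("transfer", function(s, t, dt) s[["A"]] / tau,
                            from = "A", to = "B"))),
        solution = function(t) {
          a <- a0 * exp(-t / tau)
          c(A = a, B = a0 + b0 - a)
        })
    },
    logistic_population = {
      p0 <- 1000; K <- 10000; r <- 0.04 / 12  # per month
      list(
        system = stock_flow_system(
          stocks = c(population = p0),
          flows = list(
            flow("births", function(s, t, dt) r * s[["population"]],
                 to = "population"),
            flow("deaths", function(s, t, dt)
              r * s[["population"]] * s[["population"]] / K,
              from = "population"))),
        solution = function(t)
          c(population = K / (1 + (K / p0 - 1) * exp(-r * t))))
    })
}

#' Write fixture files to a directory
#'
#' Emits the default run configuration (YAML), the reference anchors and
#' the demographic series (CSV), all generated deterministically from code.
#'
#' @param dir Target directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    config = file.path(dir, "default_config.yaml"),
    anchors = file.path(dir, "reference_anchors.csv"),
    demographics = file.path(dir, "demographic_series.csv"))
  write_config(default_config(), paths["config"])
  utils::write.csv(reference_anchors(), paths["anchors"], row.names = FALSE)
  utils::write.csv(demographic_series(), paths["demographics"],
                   row.names = FALSE)
  invisible(paths)
}
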