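# Shared test fixtures, built in code.

# Small closed journey world: no mortality (infinite life expectancy),
# constant population trend, raw transition-table onset (multiplier 1),
# hand-set initial stocks. Used by the spreadsheet-style oracle tests.
toy_journey_params <- function(trend = 1e6) {
  journey_parameters(
    healthy_life_expectancy = Inf,
    initial_dm_count = 1000,            # 900 T2DM at the 0.9 share
    fraction_developing_prediabetes = 1,
    population_trend = trend,
    initial_prediabetes = c(diagnosed = 1200, undiagnosed = 1000))
}

# Default no-intervention run, computed once per test session.
baseline_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_scenario("no_intervention")
    cache
  }
})

conservation_error <- function(result) {
  y <- result$yearly
  total <- rowSums(y[, c("normoglycemic", "undiagnosed_prediabetic",
                         "diagnosed_prediabetic", "t2dm",
                         "no_medicine_necessary")])
  drift <- total + y$cumulative_deaths - y$cumulative_inflow - total[1]
  max(abs(drift))
}
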