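test_that("clock validates its horizon and step", {
  clock <- sim_clock(1990, 2035, dt = 1)
  expect_equal(clock$n_steps, 540L)
  expect_equal(clock$times[1], 0)
  expect_equal(clock_month(clock, 2011), 252)
  expect_error(sim_clock(2000, 1990), "end_year")
  expect_error(sim_clock(1990, 2000, dt = 0), "dt")
  expect_error(sim_clock(1990, 2000, dt = 7), "integer")
  expect_error(clock_month(clock, 2040), "horizon")
})

test_that("a zero-rate outflow and an empty flow set leave stocks unchanged", {
  sys <- stock_flow_system(
    c(S = 100),
    list(flow("out", function(s, t, dt) 0, from = "S")))
  traj <- sd_integrate(sys, sim_clock(2000, 2001))
  expect_true(all(traj$stocks[, "S"] == 100))

  sys2 <- stock_flow_system(c(A = 5, B = 7), list())
  traj2 <- sd_integrate(sys2, sim_clock(2000, 2002))
  expect_true(all(traj2$stocks[, "A"] == 5))
  expect_true(all(traj2$stocks[, "B"] == 7))
})

test_that("a two-stock transfer conserves the total exactly at every step", {
  toy <- toy_system("two_stock_transfer")
  traj <- sd_integrate(toy$system, sim_clock(2000, 2005))
  expect_equal(unname(rowSums(traj$stocks)), rep(1000, length(traj$times)))
  exact <- toy$solution(traj$times[length(traj$times)])
  expect_lt(abs(traj$stocks[nrow(traj$stocks), "A"] - exact[["A"]]), 10)
})

test_that("constant inflow accumulates linearly and exactly", {
  k <- 3.25
  sys <- stock_flow_system(
    c(S = 10),
    list(flow("in", function(s, t, dt) k, to = "S")))
  clock <- sim_clock(2000, 2003, dt = 0.5)
  traj <- sd_integrate(sys, clock)
  expect_equal(unname(traj$stocks[nrow(traj$stocks), "S"]),
               10 + clock$n_steps * clock$dt * k)
})

test_that("Euler decay matches the closed form within its error bound, with error shrinking as dt halves", {
  toy <- toy_system("decay")
  exact <- toy$solution(24)[["S"]]  # 1000 * exp(-1) after 24 months
  errs <- vapply(c(1, 0.5, 0.25), function(dt) {
    traj <- sd_integrate(toy$system, sim_clock(2000, 2002, dt = dt))
    i <- match(24, traj$times)
    abs(traj$stocks[i, "S"] - exact)
  }, numeric(1))
  # global error bound for dS/dt = -S/tau: h * M/(2L) * (e^{Lt}-1),
  # L = 1/24, M = S0/tau^2
  bound <- c(1, 0.5, 0.25) * (1000 / 24^2) / (2 / 24) * (exp(1) - 1)
  expect_true(all(errs <= bound))
  expect_true(all(diff(errs) < 0))
})

test_that("the integrator agrees with an independent fixed-step implementation", {
  # deSolve's own "euler" method on the same grid is an independent coding
  # of the identical scheme; results must agree to machine precision.
  toy <- toy_system("logistic_population")
  clock <- sim_clock(2000, 2010)
  traj <- sd_integrate(toy$system, clock)
  ref <- deSolve::ode(
    y = c(population = 1000),
    times = clock$times,
    func = function(t, y, p)
      list(0.04 / 12 * y[1] - 0.04 / 12 * y[1]^2 / 10000),
    parms = NULL, method = "euler")
  expect_equal(unname(traj$stocks[, "population"]),
               unname(ref[, "population"]), tolerance = 1e-12)
})

test_that("logistic population grows monotonically and levels off below capacity", {
  toy <- toy_system("logistic_population")
  traj <- sd_integrate(toy$system, sim_clock(1900, 2100))
  p <- traj$stocks[, "population"]
  expect_true(all(diff(p) >= 0))
  expect_true(all(p <= 10000))
  n <- length(p)
  expect_lt(p[n] - p[n - 12], 2)  # yearly growth has levelled off
  expect_gt(p[n], 9000)           # near the carrying capacity
})

test_that("non-finite rates abort naming the offending flow", {
  sys <- stock_flow_system(
    c(S = 1),
    list(flow("bad_flow", function(s, t, dt) NaN, from = "S")))
  expect_error(sd_integrate(sys, sim_clock(2000, 2001)), "bad_flow")
})

test_that("negative stocks are clamped at zero and every clamp is logged", {
  sys <- stock_flow_system(
    c(S = 10),
    list(flow("drain", function(s, t, dt) 8, from = "S")))
  traj <- sd_integrate(sys, sim_clock(2000, 2001))
  expect_true(all(traj$stocks >= 0))
  expect_gt(nrow(traj$clamp_events), 0)
  expect_equal(traj$clamp_events$stock[1], "S")
  expect_equal(traj$clamp_events$amount[1], 6)  # 10 - 2*8 = -6 clamped
})

test_that("ill-formed systems are rejected before stepping", {
  expect_error(stock_flow_system(c(1, 2), list()), "named")
  expect_error(
    stock_flow_system(c(S = 1),
                      list(flow("f", function(s, t, dt) 0, from = "ghost"))),
    "ghost")
  expect_error(
    stock_flow_system(c(S = 1), list(flow("f", from = "S"))),
    "rate")
})

test_that("integration is deterministic", {
  toy <- toy_system("logistic_population")
  t1 <- sd_integrate(toy$system, sim_clock(2000, 2020))
  t2 <- sd_integrate(toy$system, sim_clock(2000, 2020))
  expect_identical(t1$stocks, t2$stocks)
  expect_identical(t1$flows, t2$flows)
})

test_that("mass balance holds step by step: total change equals net external flow", {
  r <- baseline_run()
  traj <- r$trajectory
  total <- rowSums(traj$stocks)
  external_in <- traj$flows[, "replenishment"]
  external_out <- rowSums(traj$flows[, grep("^deaths_", colnames(traj$flows)),
                                     drop = FALSE])
  step_change <- diff(total)
  expect_equal(step_change, (external_in - external_out) * traj$clock$dt,
               tolerance = 1e-9)
})
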