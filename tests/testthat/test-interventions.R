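test_that("recruitment is zero before activation and obeys the MIN structure", {
  p <- program_spec("demo", "t2dm", activation_year = 2020,
                    fraction_recruited = 0.3, success_rate = 0.3,
                    capacity = 1200)
  expect_equal(recruitment_rate(6000, p, 2019.99), 0)
  # indicated 6000*0.3/12 = 150/mo, potential 1200/12 = 100/mo
  expect_equal(recruitment_rate(6000, p, 2021), 100)
  p2 <- program_spec("demo2", "t2dm", fraction_recruited = 0.3,
                     success_rate = 0.3)
  expect_equal(recruitment_rate(6000, p2, 2021), 150)  # unlimited capacity
  inactive <- program_spec("off", "t2dm", active = FALSE,
                           fraction_recruited = 0.3, success_rate = 0.3)
  expect_equal(recruitment_rate(6000, inactive, 2030), 0)
})

test_that("the recruited fraction ramps linearly to its final value", {
  ramp <- program_spec("ramp", "t2dm", fraction_recruited = 0,
                       fraction_recruited_final = 0.3, ramp_years = 10,
                       success_rate = 0.3)
  expect_equal(current_recruited_fraction(ramp, 2025), 0.15)  # midpoint
  expect_equal(current_recruited_fraction(ramp, 2030), 0.3)
  expect_equal(current_recruited_fraction(ramp, 2045), 0.3)   # holds after
  expect_equal(recruitment_rate(1e6, ramp, 2025), 1e6 * 0.15 / 12)
  step <- program_spec("step", "t2dm", fraction_recruited = 0.28,
                       success_rate = 0.95)
  expect_equal(current_recruited_fraction(step, 2020), 0.28)
})

test_that("programme reversal and relapse flows follow their rates", {
  expect_equal(program_recovery_flow(1000, 0), 0)
  expect_equal(program_recovery_flow(1000, 0.28), 280)
  expect_equal(program_recovery_flow(1000, 0.95), 950)
  lifestyle <- program_spec("l", "t2dm")
  bariatric <- program_spec("b", "bariatric")
  expect_equal(relapse_flow(0, lifestyle), 0)
  expect_equal(relapse_flow(2400, lifestyle), 65)  # 0.65 over 2 years
  expect_equal(relapse_flow(2400, bariatric), 1)   # 0.05 over 10 years
})

test_that("relapse defaults depend on the programme target", {
  expect_equal(program_spec("a", "t2dm")$relapse_fraction, 0.65)
  expect_equal(program_spec("a", "t2dm")$relapse_time, 2)
  expect_equal(program_spec("a", "prediabetes")$relapse_fraction, 0.65)
  expect_equal(program_spec("a", "bariatric")$relapse_fraction, 0.05)
  expect_equal(program_spec("a", "bariatric")$relapse_time, 10)
})

test_that("programme specs validate their levers", {
  expect_error(program_spec("x", "t2dm", fraction_recruited = 1.2,
                            success_rate = 0.3), "fraction_recruited")
  expect_error(program_spec("x", "t2dm", success_rate = -0.1), "success_rate")
  expect_error(program_spec("x", "t2dm", cost_multiplier = 0), "cost_multiplier")
  expect_error(program_spec("x", "t2dm", relapse_time = 0), "relapse_time")
})

test_that("an active programme weakly lowers the T2DM trajectory from activation on", {
  base <- baseline_run()$yearly
  prog <- run_scenario(scenario("one_prog", list(
    program_spec("p", "t2dm", fraction_recruited = 0.1,
                 success_rate = 0.3))))$yearly
  pre <- base$year < 2020
  expect_equal(prog$t2dm[pre], base$t2dm[pre])
  expect_true(all(prog$t2dm[!pre] <= base$t2dm[!pre] + 1e-9))
  expect_lt(prog$t2dm[prog$year == 2035], base$t2dm[base$year == 2035])
})

test_that("raising the relapse fraction weakly raises the T2DM stock", {
  mk <- function(rf, rt) run_scenario(scenario("r", list(
    program_spec("p", "t2dm", fraction_recruited = 0.3, success_rate = 0.3,
                 relapse_fraction = rf, relapse_time = rt))))$yearly$t2dm
  lo <- mk(0.05, 2)
  hi <- mk(0.65, 2)
  expect_true(all(hi >= lo - 1e-9))
  expect_gt(hi[length(hi)], lo[length(lo)])
})

test_that("recruitment never exceeds the eligible stock or the capacity", {
  p <- program_spec("cap", "t2dm", fraction_recruited = 1,
                    success_rate = 1, capacity = 500)
  for (stock in c(0, 10, 1e4, 1e6)) {
    r <- recruitment_rate(stock, p, 2025)
    expect_lte(r, stock)
    expect_lte(r, 500 / 12)
  }
  r <- run_scenario(scenario("cap_run", list(p)))
  rec <- r$trajectory$flows[, "program_cap"]
  expect_true(all(rec * 1 <= 500 / 12 + 1e-12))
})

test_that("prevention programmes drain the diagnosed pre-diabetic stock to normoglycemic", {
  base <- baseline_run()$yearly
  prev <- run_scenario(scenario("prev", list(
    program_spec("pp", "prediabetes", fraction_recruited = 0.3,
                 success_rate = 0.3))))$yearly
  after <- base$year >= 2021
  expect_true(all(prev$diagnosed_prediabetic[after] <
                    base$diagnosed_prediabetic[after]))
  expect_true(all(prev$t2dm[after] < base$t2dm[after]))
  # no reversal stage for prevention targets
  expect_true(all(prev$no_medicine_necessary == 0))
})

test_that("conflicting relapse parameters across active T2DM programmes are rejected", {
  progs <- list(
    program_spec("a", "t2dm", fraction_recruited = 0.1, success_rate = 0.3),
    program_spec("b", "bariatric", fraction_recruited = 0.1,
                 success_rate = 0.9))
  expect_error(run_scenario(scenario("conflict", progs)), "relapse")
})
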