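test_that("transition rates follow fraction over time, linearly in the stock", {
  expect_equal(transition_rate(0, 0.5, 3), 0)
  # diagnosed pre-diabetics -> T2DM over 4 years at fraction 0.70
  expect_equal(transition_rate(1200, 0.70, 4), 17.5)
  # spontaneous T2DM recovery, 3 years at fraction 0.01
  expect_equal(transition_rate(1000, 0.01, 3), 1000 * 0.01 / 36)
  expect_equal(transition_rate(2000, 0.70, 4), 2 * transition_rate(1000, 0.70, 4))
  expect_error(transition_rate(100, 0.5, 0), "avg_time")
  expect_error(transition_rate(100, 1.5, 1), "fraction")
})

test_that("pre-diabetes onset splits the stock by the overweight fraction", {
  p <- journey_parameters()
  expect_equal(prediabetes_onset(0, 0.51, p), 0)
  expect_equal(prediabetes_onset(1e6, 0, p), 1e6 * 0.01 / 24)
  expect_equal(prediabetes_onset(1e6, 0.51, p),
               490000 * 0.01 / 24 + 510000 * 0.33 / 36)
  expect_error(prediabetes_onset(1e6, 1.2, p), "overweight_fraction")
})

test_that("the diagnosis split conserves the onset flow exactly", {
  expect_equal(diagnosis_split(100, 0.2, 0.1),
               c(diagnosed = 30, undiagnosed = 70))
  expect_equal(diagnosis_split(100, 0, 0),
               c(diagnosed = 0, undiagnosed = 100))
  for (onset in c(0, 17.5, 4879.17)) {
    s <- diagnosis_split(onset, 0.25, 0.25)
    expect_equal(sum(s), onset)
  }
  expect_error(diagnosis_split(100, 0.7, 0.4), "exceeds 1")
})

test_that("death rates use the shortened life expectancy per stock", {
  expect_equal(death_rate(0, 72.7), 0)
  expect_equal(death_rate(872400, 81.7 - 9), 1000)  # T2DM: 72.7 y remaining
  p <- journey_parameters()
  st <- initialize_state(p)
  d <- journey_derivatives(st, p)
  expect_equal(d[["deaths_undiagnosed"]],
               st[["undiagnosed_prediabetic"]] / ((81.7 - 10) * 12))
  expect_equal(d[["deaths_diagnosed"]],
               st[["diagnosed_prediabetic"]] / ((81.7 - 8) * 12))
  expect_equal(d[["deaths_t2dm"]], st[["t2dm"]] / ((81.7 - 9) * 12))
  expect_error(death_rate(10, 0), "remaining_life")
})

test_that("initial stocks honour the prevalence anchor and sum to the trend", {
  p <- journey_parameters()
  st <- initialize_state(p)
  expect_equal(st[["t2dm"]], 160000 * 0.9)
  expect_equal(sum(st[c("normoglycemic", "undiagnosed_prediabetic",
                        "diagnosed_prediabetic", "t2dm",
                        "no_medicine_necessary")]),
               16.0e6)
  # zero anchor: all disease stocks empty
  p0 <- journey_parameters(initial_dm_count = 0, initial_prediabetes = "zero",
                           population_trend = 18.2e6)
  st0 <- initialize_state(p0)
  expect_equal(st0[["t2dm"]], 0)
  expect_equal(st0[["normoglycemic"]], 18.2e6)
  # prevalence-fraction anchoring
  pf <- journey_parameters(initial_t2dm_fraction = 0.049 * 0.9)
  expect_equal(initialize_state(pf)[["t2dm"]], 16.0e6 * 0.049 * 0.9)
  # an anchor larger than the population is rejected
  expect_error(
    initialize_state(journey_parameters(initial_dm_count = 30e6)),
    "exceeds")
})

test_that("only onset, normoglycemic death and replenishment move an all-healthy state", {
  p <- journey_parameters(initial_dm_count = 0, initial_prediabetes = "zero")
  st <- initialize_state(p)
  d <- journey_derivatives(st, p)
  nonzero <- names(d)[d != 0]
  expect_setequal(nonzero, c("onset_diagnosed", "onset_undiagnosed",
                             "deaths_normoglycemic", "replenishment"))
})

test_that("with all transition fractions zero, stocks are constant up to demographics", {
  tr <- default_transitions()
  for (nm in names(tr)) tr[[nm]]$fraction <- 0
  p <- journey_parameters(transitions = tr, healthy_life_expectancy = Inf,
                          population_trend = 1e6,
                          initial_dm_count = 1000,
                          initial_prediabetes = c(diagnosed = 50,
                                                  undiagnosed = 70))
  r <- run_scenario(scenario("frozen"), p, cost_parameters(),
                    sim_clock(1990, 2000))
  y <- r$yearly
  expect_true(all(y$t2dm == 900))
  expect_true(all(y$diagnosed_prediabetic == 50))
  expect_true(all(y$undiagnosed_prediabetic == 70))
})

test_that("one year of journey dynamics matches a spreadsheet-style oracle", {
  p <- toy_journey_params(trend = 1e6)
  clock <- sim_clock(1990, 1991)
  st <- initialize_state(p, clock)
  traj <- sd_integrate(journey_system(p, clock = clock), clock)

  # independent step-by-step recomputation with plain arithmetic
  N <- st[["normoglycemic"]]; U <- st[["undiagnosed_prediabetic"]]
  D <- st[["diagnosed_prediabetic"]]; TT <- st[["t2dm"]]
  for (k in 1:12) {
    onset <- N * 0.49 * 0.01 / 24 + N * 0.51 * 0.33 / 36
    od <- 0.5 * onset; ou <- 0.5 * onset
    d2t <- D * 0.70 / 48; u2t <- U * 0.90 / 84
    drec <- D * 0.30 / 24; urec <- U * 0.10 / 48; trec <- TT * 0.01 / 36
    repl <- 1e6 - (N + U + D + TT)
    N <- N - onset + drec + urec + trec + repl
    U <- U + ou - u2t - urec
    D <- D + od - d2t - drec
    TT <- TT + d2t + u2t - trec
    got <- traj$stocks[k + 1, ]
    expect_equal(got[["normoglycemic"]], N, tolerance = 1e-9)
    expect_equal(got[["undiagnosed_prediabetic"]], U, tolerance = 1e-9)
    expect_equal(got[["diagnosed_prediabetic"]], D, tolerance = 1e-9)
    expect_equal(got[["t2dm"]], TT, tolerance = 1e-9)
  }
})

test_that("population is conserved over the full default run", {
  expect_lt(conservation_error(baseline_run()), 1)
})

test_that("the total population follows the exogenous trend", {
  r <- baseline_run()
  y <- r$yearly
  total <- rowSums(y[, c("normoglycemic", "undiagnosed_prediabetic",
                         "diagnosed_prediabetic", "t2dm",
                         "no_medicine_necessary")])
  trend <- population_trend_default(y$year)$population
  expect_equal(total, trend, tolerance = 1e-9)
})

test_that("T2DM responds monotonically to onset and recovery fractions", {
  clock <- sim_clock(1990, 2010)
  t2dm_with <- function(path, value) {
    p <- journey_parameters()
    p <- t2djourney:::param_set(p, path, value)
    run_scenario(scenario("x"), p, cost_parameters(), clock)$yearly$t2dm
  }
  base <- run_scenario(scenario("base"), journey_parameters(),
                       cost_parameters(), clock)$yearly$t2dm
  # raising an onset fraction never lowers the T2DM stock anywhere
  up_onset <- t2dm_with("transitions.onset_overweight.fraction", 0.40)
  expect_true(all(up_onset >= base - 1e-9))
  # raising a recovery fraction never raises it
  up_rec <- t2dm_with("transitions.t2dm_recovery.fraction", 0.05)
  expect_true(all(up_rec <= base + 1e-9))
  up_rec2 <- t2dm_with("transitions.diagnosed_recovery.fraction", 0.6)
  expect_true(all(up_rec2 <= base + 1e-9))
})

test_that("without recovery the T2DM stock never decreases while onset is positive", {
  tr <- default_transitions()
  tr$diagnosed_recovery$fraction <- 0
  tr$undiagnosed_recovery$fraction <- 0
  tr$t2dm_recovery$fraction <- 0
  p <- journey_parameters(transitions = tr)
  r <- run_scenario(scenario("reinforcing"), p, cost_parameters(),
                    sim_clock(1990, 2020))
  expect_true(all(diff(r$trajectory$stocks[, "t2dm"]) >= -1e-9))
})

test_that("simulated prevalence grows monotonically through 2019 between the printed anchors", {
  y <- baseline_run()$yearly
  upto2019 <- y$t2dm[y$year <= 2019]
  expect_true(all(diff(upto2019) > 0))
  # DM prevalence between 1% (1990) and ~4.9% (2011), within 20%
  dm_frac_1990 <- y$dm_estimate[y$year == 1990] / 16.0e6
  dm_frac_2011 <- y$dm_estimate[y$year == 2011] / 16.94e6
  expect_equal(dm_frac_1990, 0.01, tolerance = 0.2)
  expect_equal(dm_frac_2011, 0.049, tolerance = 0.2)
})

test_that("parameter invariants are enforced", {
  expect_error(journey_parameters(ifg_fraction = 0.7, igt_fraction = 0.4),
               "exceed 1")
  expect_error(journey_parameters(healthy_life_expectancy = 50,
                                  lifespan_shortening = c(
                                    undiagnosed_prediabetic = 60,
                                    diagnosed_prediabetic = 8, t2dm = 9)),
               "shortening")
  tr <- default_transitions(); tr$diagnosed_to_t2dm$fraction <- 1.4
  expect_error(journey_parameters(transitions = tr), "\\[0, 1\\]")
})
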