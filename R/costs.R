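# Societal cost accounting: population stocks and programme activity are
# translated into annual costs by payer (authorities, health insurer,
# employer, patient-organisation management, programmes).

#' Per-patient unit cost parameters
#'
#' Annual unit costs in euros per person per year, by component. The source
#' model's cost parameterisation is not publicly available; these defaults
#' are calibrated placeholders: realistic Dutch orders of magnitude, scaled
#' once so the default no-intervention run reaches about 13 billion euros
#' total annual societal cost in 2035 (see the methods vignette). Components
#' quoted for the whole diabetes population (`comorbidity`,
#' `dm_management_orgs`) are scaled to type 2 by the 0.9 share.
#'
#' @param wia_iva_benefit,wga_benefit Disability benefits (authorities) paid
#'   for the `disability_fraction` of employed T2DM patients.
#' @param employer_salary_continuation Statutory salary continuation for
#'   disabled employees (employer), same disability fraction.
#' @param productivity_loss Labour productivity loss per employed T2DM
#'   patient (employer).
#' @param ambulatory_care,hospitalization,physiotherapy,tools_devices,gp_care
#'   Medical care components (insurer).
#' @param medication_standard,medication_elderly Medication unit costs,
#'   blended by `elderly_fraction` (insulin dosing differs in the elderly).
#' @param comorbidity T2DM comorbidity care (insurer; DM-wide, scaled 0.9).
#' @param dm_management_orgs Patient-organisation/management cost per
#'   patient (DM-wide, scaled 0.9).
#' @param disability_fraction Share of employed T2DM patients claiming
#'   disability benefits.
#' @param elderly_fraction Elderly share of the patient population (scalar
#'   or `year`/value series).
#' @param employment_fraction Share of patients employed (the model assumes
#'   full employment by default).
#' @param prediab_productivity_weight Productivity-loss weight applied to
#'   pre-diabetic stocks relative to T2DM patients.
#' @param base_program_cost Standard lifestyle programme cost per recruited
#'   participant per year (cost multiplier 1).
#' @param bariatric_unit_cost_range Reported bariatric surgery cost band
#'   (euros); the 17x multiplier times `base_program_cost` must fall in it.
#' @return Object of class `cost_parameters`.
#' @export
cost_parameters <- function(wia_iva_benefit = 13400,
                            wga_benefit = 9000,
                            employer_salary_continuation = 27000,
                            productivity_loss = 2500,
                            ambulatory_care = 800,
                            hospitalization = 1200,
                            physiotherapy = 230,
                            tools_devices = 340,
                            gp_care = 300,
                            medication_standard = 900,
                            medication_elderly = 1570,
                            comorbidity = 2200,
                            dm_management_orgs = 125,
                            disability_fraction = 0.05,
                            elderly_fraction = 0.20,
                            employment_fraction = 1.0,
                            prediab_productivity_weight = 0.3,
                            base_program_cost = 1000,
                            bariatric_unit_cost_range = c(15000, 20000)) {
  p <- structure(mget(names(formals())), class = "cost_parameters")
  unit_costs <- c("wia_iva_benefit", "wga_benefit",
                  "employer_salary_continuation", "productivity_loss",
                  "ambulatory_care", "hospitalization", "physiotherapy",
                  "tools_devices", "gp_care", "medication_standard",
                  "medication_elderly", "comorbidity", "dm_management_orgs",
                  "base_program_cost")
  for (nm in unit_costs) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v))
      stop(sprintf("cost_parameters: missing or invalid unit cost '%s'", nm))
    if (v < 0)
      stop(sprintf("cost_parameters: unit cost '%s' must be >= 0", nm))
  }
  for (nm in c("disability_fraction", "employment_fraction",
               "prediab_productivity_weight")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("cost_parameters: '%s' must lie in [0, 1]", nm))
  }
  p
}

T2DM_SHARE <- 0.9  # DM-wide unit costs scaled to the type 2 share

#' Annual societal cost breakdown at a state
#'
#' Computes each payer's annual cost as (relevant population) x (unit cost)
#' x (relevant fraction), linear in every stock: disability benefits paid by
#' the authorities, medical care paid by the insurer (medication blended by
#' the elderly fraction), productivity loss and salary continuation borne by
#' the employer, patient-organisation management, and programme costs
#' (recruited participants per year times the standard programme cost times
#' the programme's cost multiplier). Pre-diabetic stocks contribute GP care
#' (diagnosed only) and weighted productivity loss.
#'
#' @param state Named numeric vector with the journey stocks.
#' @param params A [cost_parameters()] object.
#' @param programs List of active [program_spec()]s; their recruitment is
#'   evaluated at `state` and `year`.
#' @param year Calendar year of the breakdown.
#' @return Object of class `cost_breakdown`: named list with components
#'   `authorities`, `insurer`, `employer`, `dm_management`, `program` and
#'   their `total` (euros per year).
#' @export
annual_cost <- function(state, params, programs = list(), year = 2020) {
  t2dm <- state[["t2dm"]]
  diag <- state[["diagnosed_prediabetic"]]
  undiag <- state[["undiagnosed_prediabetic"]]
  elderly <- series_at(params$elderly_fraction, year)
  employed <- params$employment_fraction

  authorities <- t2dm * employed * params$disability_fraction *
    (params$wia_iva_benefit + params$wga_benefit)

  medication <- (1 - elderly) * params$medication_standard +
    elderly * params$medication_elderly
  insurer <- t2dm * (params$ambulatory_care + params$hospitalization +
                       params$physiotherapy + params$tools_devices +
                       params$gp_care + medication +
                       params$comorbidity * T2DM_SHARE) +
    diag * params$gp_care

  employer <- t2dm * employed *
    (params$productivity_loss +
       params$disability_fraction * params$employer_salary_continuation) +
    (diag + undiag) * employed * params$productivity_loss *
    params$prediab_productivity_weight

  dm_management <- t2dm * params$dm_management_orgs * T2DM_SHARE

  program <- 0
  for (prog in programs) {
    if (!prog$active) next
    eligible <- if (prog$target == "prediabetes") diag else t2dm
    recruited_yr <- 12 * recruitment_rate(eligible, prog, year)
    program <- program + recruited_yr * params$base_program_cost *
      prog$cost_multiplier
  }

  out <- list(authorities = unname(authorities),
              insurer = unname(insurer),
              employer = unname(employer),
              dm_management = unname(dm_management),
              program = unname(program))
  out$total <- sum(unlist(out))
  structure(out, class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> (EUR/year)\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %16.0f\n", nm, x[[nm]]))
  invisible(x)
}

#' Annual cost series along yearly snapshots
#'
#' @param yearly Data frame of yearly states (one row per year, stock
#'   columns as produced by [run_scenario()]).
#' @param params A [cost_parameters()] object.
#' @param programs List of [program_spec()]s.
#' @return Data frame: year, one column per payer, `total`.
#' @export
annual_cost_series <- function(yearly, params, programs = list()) {
  rows <- lapply(seq_len(nrow(yearly)), function(i) {
    st <- as.numeric(yearly[i, JOURNEY_STOCKS])
    names(st) <- JOURNEY_STOCKS
    bd <- annual_cost(st, params, programs, year = yearly$year[i])
    data.frame(year = yearly$year[i], as.data.frame(unclass(bd)))
  })
  do.call(rbind, rows)
}

#' Cumulative cost series
#'
#' Running sum of annual totals; non-decreasing for non-negative annual
#' costs.
#'
#' @param costs Data frame from [annual_cost_series()] (or any data frame
#'   with a `total` column), or a numeric vector of annual totals.
#' @return Numeric vector of cumulative euros.
#' @export
cumulative_cost <- function(costs) {
  totals <- if (is.data.frame(costs)) costs$total else costs
  cumsum(totals)
}
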