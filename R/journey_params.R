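# Parameterisation of the patient-journey model: transition table, life
# expectancies, diagnosis split, exogenous demographic series.

#' Default stock-to-stock transition table
#'
#' Each entry holds the fraction of the source stock making the transition
#' and the average time (years) it takes, so the flow rate is
#' `stock * fraction / (avg_time * 12)` persons per month (see
#' [transition_rate()]).
#'
#' @return Named list of `(fraction, avg_time)` pairs.
#' @export
default_transitions <- function() {
  tr <- function(fraction, avg_time) list(fraction = fraction, avg_time = avg_time)
  list(
    onset_nonoverweight  = tr(0.01, 2),  # normoglycemic (non-overweight) -> pre-diabetic
    onset_overweight     = tr(0.33, 3),  # normoglycemic (overweight) -> pre-diabetic
    diagnosed_to_t2dm    = tr(0.70, 4),
    undiagnosed_to_t2dm  = tr(0.90, 7),
    diagnosed_recovery   = tr(0.30, 2),  # diagnosed pre-diabetic -> normoglycemic
    undiagnosed_recovery = tr(0.10, 4),
    t2dm_recovery        = tr(0.01, 3),  # spontaneous reversal, no programme
    relapse_lifestyle    = tr(0.65, 2),  # no-medicine -> T2DM after lifestyle reversal
    relapse_bariatric    = tr(0.05, 10)  # no-medicine -> T2DM after bariatric surgery
  )
}

#' Alternate recovery-fraction variant of the transition table
#'
#' The source material states the pre-diabetes recovery fractions in two
#' places with different values (0.30/0.10 in the transition table versus
#' 0.10/0.05 in the accompanying text). The table values are the default;
#' this helper returns the text variant for comparison runs.
#' @return Named list as in [default_transitions()].
#' @export
alternate_recovery_transitions <- function() {
  tr <- default_transitions()
  tr$diagnosed_recovery$fraction <- 0.10
  tr$undiagnosed_recovery$fraction <- 0.05
  tr
}

#' Default Dutch population trend
#'
#' Linear interpolation through the population levels implied by the
#' reported national diabetes counts and prevalences: 16.0 million in 1990
#' (160,000 DM patients at 1% prevalence), 16.94 million in 2011 (830,000 at
#' ~4.9%), 18.2 million in 2019 (1.2 million at 6.6%), held flat to 2035.
#'
#' @param years Years to evaluate (default 1990..2035).
#' @return Data frame with columns `year` and `population`.
#' @export
population_trend_default <- function(years = 1990:2035) {
  anchors_y <- c(1990, 2011, 2019, 2035)
  anchors_p <- c(16.0e6, 16.94e6, 18.2e6, 18.2e6)
  data.frame(
    year = years,
    population = stats::approx(anchors_y, anchors_p, xout = years,
                               rule = 2)$y)
}

# Evaluate a scalar-or-series exogenous input at (possibly fractional) years.
series_at <- function(x, year) {
  if (is.data.frame(x)) {
    value_col <- setdiff(names(x), "year")[1]
    stats::approx(x$year, x[[value_col]], xout = year, rule = 2)$y
  } else {
    rep_len(x, length(year))
  }
}

#' Journey model parameters
#'
#' Bundles everything the patient-journey stock-flow structure needs: the
#' transition table, the diagnosis incidence split (IFG/IGT), life
#' expectancies, the initial prevalence anchor, and the exogenous
#' demographic series. All times are stated in years and converted to months
#' inside the rate functions.
#'
#' `fraction_developing_prediabetes` scales the pre-diabetes onset flow; it
#' stands in for the exogenous onset incidence variables whose source values
#' are not publicly available, and its default is calibrated so the
#' no-intervention run tracks the national reference anchors (see the
#' methods vignette). `ifg_fraction`/`igt_fraction` are likewise
#' placeholders chosen to split onset 50:50 into diagnosed/undiagnosed.
#'
#' @param transitions Transition table, see [default_transitions()].
#' @param ifg_fraction,igt_fraction Incidence fractions routing new
#'   pre-diabetics to the diagnosed stock; their sum must not exceed 1.
#' @param healthy_life_expectancy Years; Dutch average 81.7.
#' @param lifespan_shortening Named years of life lost for
#'   `undiagnosed_prediabetic` (10), `diagnosed_prediabetic` (8), `t2dm` (9).
#' @param t2dm_fraction_of_dm Share of all diabetes that is type 2 (0.9).
#' @param initial_dm_count Total DM patients at the start year; the initial
#'   T2DM stock is this times `t2dm_fraction_of_dm`. Default 160,000 (1990).
#' @param initial_t2dm_fraction Optional prevalence-anchor alternative: when
#'   set, the initial T2DM stock is `trend(start_year) *
#'   initial_t2dm_fraction` and `initial_dm_count` is ignored (use e.g.
#'   `0.049 * 0.9` for the 2011-prevalence anchoring described in the
#'   vignette).
#' @param fraction_developing_prediabetes Dimensionless multiplier on the
#'   pre-diabetes onset flow (calibrated placeholder).
#' @param population_trend Data frame `year`/`population` or a scalar.
#' @param overweight_fraction,obese_fraction Scalars or `year`/value series.
#' @param initial_prediabetes `"steady_state"` (seed the two pre-diabetic
#'   stocks at values consistent with the initial onset flow), `"zero"`, or
#'   a named numeric `c(diagnosed = , undiagnosed = )` of persons.
#' @return Object of class `journey_parameters` (a validated list).
#' @export
journey_parameters <- function(transitions = default_transitions(),
                               ifg_fraction = 0.25,
                               igt_fraction = 0.25,
                               healthy_life_expectancy = 81.7,
                               lifespan_shortening = c(
                                 undiagnosed_prediabetic = 10,
                                 diagnosed_prediabetic = 8,
                                 t2dm = 9),
                               t2dm_fraction_of_dm = 0.9,
                               initial_dm_count = 160000,
                               initial_t2dm_fraction = NULL,
                               fraction_developing_prediabetes = 0.057,
                               population_trend = population_trend_default(),
                               overweight_fraction = 0.51,
                               obese_fraction = 0.15,
                               initial_prediabetes = "steady_state") {
  params <- structure(
    list(transitions = transitions,
         ifg_fraction = ifg_fraction,
         igt_fraction = igt_fraction,
         healthy_life_expectancy = healthy_life_expectancy,
         lifespan_shortening = lifespan_shortening,
         t2dm_fraction_of_dm = t2dm_fraction_of_dm,
         initial_dm_count = initial_dm_count,
         initial_t2dm_fraction = initial_t2dm_fraction,
         fraction_developing_prediabetes = fraction_developing_prediabetes,
         population_trend = population_trend,
         overweight_fraction = overweight_fraction,
         obese_fraction = obese_fraction,
         initial_prediabetes = initial_prediabetes),
    class = "journey_parameters")
  validate_journey_parameters(params)
  params
}

validate_journey_parameters <- function(p) {
  chk_frac <- function(x, what) {
    if (!is.numeric(x) || any(x < 0 | x > 1))
      stop(sprintf("journey_parameters: %s must lie in [0, 1]", what))
  }
  for (nm in names(p$transitions)) {
    tr <- p$transitions[[nm]]
    chk_frac(tr$fraction, sprintf("transitions$%s$fraction", nm))
    if (!is.numeric(tr$avg_time) || tr$avg_time <= 0)
      stop(sprintf("journey_parameters: transitions$%s$avg_time must be > 0", nm))
  }
  chk_frac(p$ifg_fraction, "ifg_fraction")
  chk_frac(p$igt_fraction, "igt_fraction")
  if (p$ifg_fraction + p$igt_fraction > 1)
    stop("journey_parameters: ifg_fraction + igt_fraction must not exceed 1")
  chk_frac(p$t2dm_fraction_of_dm, "t2dm_fraction_of_dm")
  if (!is.numeric(p$fraction_developing_prediabetes) ||
      p$fraction_developing_prediabetes < 0)
    stop("journey_parameters: fraction_developing_prediabetes must be >= 0")
  if (p$healthy_life_expectancy <= 0)
    stop("journey_parameters: healthy_life_expectancy must be > 0")
  need <- c("undiagnosed_prediabetic", "diagnosed_prediabetic", "t2dm")
  if (!all(need %in% names(p$lifespan_shortening)))
    stop("journey_parameters: lifespan_shortening must name ",
         paste(need, collapse = ", "))
  if (any(p$lifespan_shortening >= p$healthy_life_expectancy))
    stop("journey_parameters: lifespan shortening must be below the healthy life expectancy")
  if (is.data.frame(p$population_trend)) {
    if (any(p$population_trend$population < 0))
      stop("journey_parameters: population trend must be non-negative")
  } else if (p$population_trend < 0) {
    stop("journey_parameters: population trend must be non-negative")
  }
  if (!is.data.frame(p$overweight_fraction))
    chk_frac(p$overweight_fraction, "overweight_fraction")
  if (!is.data.frame(p$obese_fraction))
    chk_frac(p$obese_fraction, "obese_fraction")
  invisible(p)
}

# Remaining life expectancy (years) for a journey stock.
remaining_life <- function(params, stock) {
  short <- switch(stock,
                  undiagnosed_prediabetic = ,
                  diagnosed_prediabetic = ,
                  t2dm = unname(params$lifespan_shortening[stock]),
                  0)
  params$healthy_life_expectancy - short
}

# Dotted-path access into nested parameter lists, used by the sensitivity
# analysis ("transitions.onset_overweight.fraction", "ifg_fraction", ...).
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!k %in% names(node))
      stop(sprintf("unknown parameter '%s' (at '%s')", path, k))
    node <- node[[k]]
  }
  node
}

param_set <- function(params, path, value) {
  param_get(params, path)  # validates the path exists
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  assign_in <- function(node, keys) {
    if (length(keys) == 1L) {
      node[[keys]] <- value
    } else {
      node[[keys[1L]]] <- assign_in(node[[keys[1L]]], keys[-1L])
    }
    node
  }
  assign_in(params, keys)
}
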