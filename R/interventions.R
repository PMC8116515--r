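# Intervention and prevention programme levers: capacity-limited recruitment
# with optional linear ramp-up, programme success routing into the reversal
# ("no medicine necessary") stock, and relapse behaviour.

#' Specify an intervention programme
#'
#' A programme recruits a fraction of its eligible stock each year (T2DM
#' patients for `"t2dm"` and `"bariatric"` targets, diagnosed pre-diabetics
#' for `"prediabetes"`), and its successful participants leave the disease
#' stock: T2DM-targeted successes move to the "no medicine necessary" stock
#' (subject to relapse), prevention successes return directly to the
#' normoglycemic stock. Relapse defaults are 65% over 2 years for lifestyle
#' programmes and 5% over 10 years for bariatric surgery.
#'
#' @param name Programme label (used in flow/column names).
#' @param target One of `"t2dm"`, `"prediabetes"`, `"bariatric"`.
#' @param active Logical; inactive programmes contribute no flows.
#' @param activation_year Calendar year the programme switches on (January).
#' @param fraction_recruited Recruited fraction of the eligible stock per
#'   year at activation.
#' @param fraction_recruited_final Fraction reached at the end of the ramp;
#'   defaults to `fraction_recruited` (step activation).
#' @param ramp_years Years of linear ramp from `fraction_recruited` to
#'   `fraction_recruited_final` (0 = step).
#' @param success_rate Share of recruited participants whose reversal
#'   succeeds; the remainder stay in the source stock.
#' @param cost_multiplier Programme price relative to the standard
#'   per-participant programme cost (1 = standard).
#' @param capacity Optional maximum participants per year.
#' @param relapse_fraction,relapse_time Share of reversed patients relapsing
#'   into the T2DM stock and the characteristic time (years); defaults by
#'   target as above.
#' @return Object of class `program_spec`.
#' @export
program_spec <- function(name,
                         target = c("t2dm", "prediabetes", "bariatric"),
                         active = TRUE,
                         activation_year = 2020,
                         fraction_recruited = 0,
                         fraction_recruited_final = fraction_recruited,
                         ramp_years = 0,
                         success_rate = 0,
                         cost_multiplier = 1,
                         capacity = NULL,
                         relapse_fraction = NULL,
                         relapse_time = NULL) {
  target <- match.arg(target)
  if (is.null(relapse_fraction))
    relapse_fraction <- if (target == "bariatric") 0.05 else 0.65
  if (is.null(relapse_time))
    relapse_time <- if (target == "bariatric") 10 else 2
  spec <- structure(
    list(name = name, target = target, active = isTRUE(active),
         activation_year = activation_year,
         fraction_recruited = fraction_recruited,
         fraction_recruited_final = fraction_recruited_final,
         ramp_years = ramp_years,
         success_rate = success_rate,
         cost_multiplier = cost_multiplier,
         capacity = capacity,
         relapse_fraction = relapse_fraction,
         relapse_time = relapse_time),
    class = "program_spec")
  validate_program_spec(spec)
  spec
}

validate_program_spec <- function(p) {
  if (!inherits(p, "program_spec"))
    stop("programs must be built with program_spec()")
  frac <- c(fraction_recruited = p$fraction_recruited,
            fraction_recruited_final = p$fraction_recruited_final,
            success_rate = p$success_rate,
            relapse_fraction = p$relapse_fraction)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    stop(sprintf("program_spec '%s': %s must lie in [0, 1]",
                 p$name, paste(names(frac)[bad], collapse = ", ")))
  if (p$cost_multiplier <= 0)
    stop(sprintf("program_spec '%s': cost_multiplier must be > 0", p$name))
  if (p$ramp_years < 0)
    stop(sprintf("program_spec '%s': ramp_years must be >= 0", p$name))
  if (p$relapse_time <= 0)
    stop(sprintf("program_spec '%s': relapse_time must be > 0", p$name))
  if (!is.null(p$capacity) && p$capacity < 0)
    stop(sprintf("program_spec '%s': capacity must be >= 0", p$name))
  invisible(p)
}

#' Recruited fraction of the eligible stock at a time point
#'
#' Zero before activation; from activation the fraction ramps linearly from
#' `fraction_recruited` to `fraction_recruited_final` over `ramp_years`
#' (constant at `fraction_recruited` when `ramp_years` is 0).
#'
#' @param spec A [program_spec()].
#' @param t_year Calendar time in (possibly fractional) years.
#' @return Recruited fraction per year.
#' @export
current_recruited_fraction <- function(spec, t_year) {
  if (!spec$active || t_year < spec$activation_year) return(0)
  if (spec$ramp_years <= 0) return(spec$fraction_recruited)
  progress <- min(1, (t_year - spec$activation_year) / spec$ramp_years)
  spec$fraction_recruited +
    (spec$fraction_recruited_final - spec$fraction_recruited) * progress
}

#' Programme recruitment rate
#'
#' The realised recruitment is the minimum of the indicated rate (eligible
#' stock times the current recruited fraction) and the potential rate set by
#' the programme's treatment capacity — the MIN structure of the programme
#' submodule. Recruitment can never exceed the eligible stock itself.
#'
#' @param eligible_stock Persons eligible for the programme.
#' @param spec A [program_spec()].
#' @param t_year Calendar time in years.
#' @return Recruitment rate in persons per month.
#' @examples
#' p <- program_spec("demo", "t2dm", fraction_recruited = 0.3,
#'                   success_rate = 0.3, capacity = 1200)
#' recruitment_rate(6000, p, 2020)  # min(150, 100) = 100 persons/month
#' @export
recruitment_rate <- function(eligible_stock, spec, t_year) {
  if (eligible_stock < 0)
    stop("recruitment_rate: eligible_stock must be non-negative")
  indicated <- eligible_stock * current_recruited_fraction(spec, t_year) / 12
  potential <- if (is.null(spec$capacity)) Inf else spec$capacity / 12
  min(indicated, potential, eligible_stock)
}

#' Successful-reversal flow of a programme
#'
#' Of the recruited participants, the programme's success rate determines
#' the flow leaving the disease stock (T2DM to "no medicine necessary", or
#' diagnosed pre-diabetes to normoglycemic for prevention programmes); the
#' unsuccessful remainder stays put.
#'
#' @param recruited Recruitment rate (persons per month).
#' @param success_rate Programme success rate in \[0, 1\].
#' @return Reversal flow in persons per month.
#' @export
program_recovery_flow <- function(recruited, success_rate) {
  if (success_rate < 0 || success_rate > 1)
    stop("program_recovery_flow: success_rate must lie in [0, 1]")
  recruited * success_rate
}

#' Relapse flow out of the "no medicine necessary" stock
#'
#' The relapse fraction of reversed patients returns to the T2DM stock over
#' the relapse time; the complementary fraction exits to the normoglycemic
#' stock over the same characteristic time (sustained recovery).
#'
#' @param no_medicine_stock Persons currently off medication.
#' @param spec A [program_spec()] supplying `relapse_fraction` and
#'   `relapse_time`.
#' @return Relapse rate in persons per month.
#' @examples
#' lifestyle <- program_spec("p", "t2dm")
#' relapse_flow(2400, lifestyle)  # 2400 * 0.65 / 24 = 65 persons/month
#' @export
relapse_flow <- function(no_medicine_stock, spec) {
  if (no_medicine_stock < 0)
    stop("relapse_flow: stock must be non-negative")
  no_medicine_stock * spec$relapse_fraction / (spec$relapse_time * 12)
}
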