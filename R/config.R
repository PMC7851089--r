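#' Health states of the cohort model
#'
#' The model tracks eight mutually exclusive states: the two glycemic states
#' (`uncontrolled`, `controlled`), four chronic complications (`cvd`,
#' `retinopathy`, `nephropathy`, `diabetic_foot`), an acute one-cycle
#' `hospitalization` state, and the absorbing `dead` state.
#'
#' @return Character vector of state names, in canonical order.
#' @export
health_states <- function() {
  c("uncontrolled", "controlled", "cvd", "retinopathy", "nephropathy",
    "hospitalization", "diabetic_foot", "dead")
}

#' Names of the complication states
#' @return Character vector of the five complication state names.
#' @keywords internal
complication_states <- function() {
  c("cvd", "retinopathy", "nephropathy", "hospitalization", "diabetic_foot")
}

#' Average cost of the diabetic-foot state
#'
#' The diabetic-foot state cost is the mean of the published sub-costs for
#' foot with healing, minor amputation and major amputation (US$/patient/year).
#'
#' @param sub_costs Numeric vector of sub-costs. Defaults to the reference
#'   values 162.10, 112.90 and 223.80 US$/patient/year.
#' @return Single annual cost in US$.
#' @examples
#' diabetic_foot_cost()  # 166.27
#' @export
diabetic_foot_cost <- function(sub_costs = c(162.10, 112.90, 223.80)) {
  stopifnot(is.numeric(sub_costs), length(sub_costs) >= 1, all(sub_costs >= 0))
  mean(sub_costs)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1], got %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop(sprintf("`%s` must be a non-negative number, got %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(x)
}

check_prob_vec <- function(x, name, states) {
  if (!all(states %in% names(x)))
    stop(sprintf("`%s` must name all of: %s", name,
                 paste(states, collapse = ", ")), call. = FALSE)
  for (s in states) check_prob(x[[s]], paste0(name, ".", s))
  invisible(x)
}

#' Define a testing strategy
#'
#' A strategy bundles the per-cycle probability of bringing an uncontrolled
#' patient to the glycemic target, the unit testing costs, and the fraction of
#' patients for whom an A1c result is actually available under that testing
#' route.
#'
#' @param name Strategy label, e.g. `"poc"` or `"lab"`.
#' @param control_prob_per_cycle Per-cycle probability that an uncontrolled
#'   patient reaches the A1c target under this strategy.
#' @param test_cost_per_test Consumable cost per test in US$ (cartridge for the
#'   point-of-care device, laboratory fee for the central laboratory).
#' @param device_cost Purchase cost of the testing device in US$ (0 when no
#'   device is required).
#' @param device_tests_lifetime Number of tests over which the device cost is
#'   amortized; each test carries `device_cost / device_tests_lifetime`.
#' @param tests_per_cycle Tests performed per alive patient per cycle.
#' @param a1c_availability Fraction of patients with an A1c result available
#'   under this strategy (used by the `assessed_control` effectiveness
#'   definition; 1 means universal access).
#' @return An object of class `a1c_strategy`.
#' @export
strategy_spec <- function(name,
                          control_prob_per_cycle,
                          test_cost_per_test,
                          device_cost = 0,
                          device_tests_lifetime = 5000,
                          tests_per_cycle = 1,
                          a1c_availability = 1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  check_prob(control_prob_per_cycle, "control_prob_per_cycle")
  check_nonneg(test_cost_per_test, "test_cost_per_test")
  check_nonneg(device_cost, "device_cost")
  check_nonneg(tests_per_cycle, "tests_per_cycle")
  check_prob(a1c_availability, "a1c_availability")
  if (device_cost > 0 && (!is.numeric(device_tests_lifetime) ||
                          device_tests_lifetime <= 0))
    stop("`device_tests_lifetime` must be > 0 when `device_cost` > 0",
         call. = FALSE)
  structure(list(
    name = name,
    control_prob_per_cycle = control_prob_per_cycle,
    test_cost_per_test = test_cost_per_test,
    device_cost = device_cost,
    device_tests_lifetime = device_tests_lifetime,
    tests_per_cycle = tests_per_cycle,
    a1c_availability = a1c_availability
  ), class = "a1c_strategy")
}

#' Build a model configuration
#'
#' The configuration is the complete parameter ledger of the decision problem:
#' cycle structure, discounting, state costs, annual occurrence and
#' case-fatality probabilities of the complications, the effectiveness
#' definition, and the strategies under comparison.
#'
#' Annual probabilities are converted internally to per-cycle probabilities
#' with [annual_to_cycle_prob()]. Effectiveness definitions:
#' \describe{
#'   \item{`cumulative_ever`}{probability of having reached the `controlled`
#'     state by `effectiveness_eval_cycles` (first passage, from the trace).}
#'   \item{`at_eval_point`}{occupancy of `controlled` at the evaluation cycle.}
#'   \item{`discounted_time_in_control`}{discounted fraction of the horizon
#'     spent in control.}
#'   \item{`assessed_control`}{probability that a patient has an A1c result
#'     available and reaches the target within the evaluation window,
#'     computed from the assessment process:
#'     `a1c_availability * (1 - (1 - p)^effectiveness_eval_cycles)`.}
#' }
#'
#' @param cycle_length_months Cycle length in months (default 3, the A1c
#'   reassessment interval).
#' @param horizon_years Model horizon in years (default 10).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   outcomes (default 0.04).
#' @param half_cycle_correction Apply trapezoidal half-cycle correction when
#'   accruing costs (default `TRUE`).
#' @param target_a1c Glycemic target in percent A1c (default 7.5; descriptive,
#'   the model works on control probabilities).
#' @param effectiveness_definition One of `"cumulative_ever"`,
#'   `"at_eval_point"`, `"discounted_time_in_control"`, `"assessed_control"`.
#' @param effectiveness_eval_cycles Evaluation window in cycles for the
#'   effectiveness definitions (default 2, i.e. 6 months with quarterly
#'   cycles).
#' @param general_annual_cost Annual cost of routine diabetes care accruing to
#'   every alive patient, US$/patient/year (default 1844.00).
#' @param complication_costs_annual Named annual costs (US$/patient/year) for
#'   `cvd`, `retinopathy`, `nephropathy`, `hospitalization`, `diabetic_foot`.
#' @param occurrence_probs_annual Named annual probabilities of developing each
#'   complication while uncontrolled.
#' @param death_probs_annual Named annual case-fatality probabilities for
#'   occupants of each complication state.
#' @param complication_risk_rr_controlled Relative risk of complications for
#'   controlled vs uncontrolled patients (default 0: reaching the target
#'   removes complication risk).
#' @param relapse_prob_per_cycle Per-cycle probability that a controlled
#'   patient relapses to uncontrolled (default 0).
#' @param background_mortality_annual Annual all-cause mortality applied to
#'   every alive state in addition to complication case fatality (default 0).
#' @param hospitalization_cost_per_event If `TRUE`, the hospitalization cost is
#'   charged in full for each cycle spent in the one-cycle hospitalization
#'   state (per-admission cost); if `FALSE` it is prorated like the chronic
#'   annual costs (default `FALSE`).
#' @param strategies List of [strategy_spec()] objects (at least one; two for
#'   an incremental comparison).
#' @return An object of class `a1c_model_config`.
#' @seealso [reference_config()] for the fully calibrated reference
#'   parameterization.
#' @export
model_config <- function(cycle_length_months = 3,
                         horizon_years = 10,
                         annual_discount_rate = 0.04,
                         half_cycle_correction = TRUE,
                         target_a1c = 7.5,
                         effectiveness_definition = c("cumulative_ever",
                                                      "at_eval_point",
                                                      "discounted_time_in_control",
                                                      "assessed_control"),
                         effectiveness_eval_cycles = 2,
                         general_annual_cost = 1844.00,
                         complication_costs_annual = c(
                           cvd = 1529.00, retinopathy = 621.00,
                           nephropathy = 1602.00, hospitalization = 3917.00,
                           diabetic_foot = diabetic_foot_cost()),
                         occurrence_probs_annual = c(
                           cvd = 0.129, retinopathy = 0.1340,
                           nephropathy = 0.1680, hospitalization = 0.1895,
                           diabetic_foot = 0.0310),
                         death_probs_annual = c(
                           cvd = 0.2840, retinopathy = 0.0000,
                           nephropathy = 0.0381, hospitalization = 0.0617,
                           diabetic_foot = 0.0740),
                         complication_risk_rr_controlled = 0,
                         relapse_prob_per_cycle = 0,
                         background_mortality_annual = 0,
                         hospitalization_cost_per_event = FALSE,
                         strategies = list()) {
  effectiveness_definition <- match.arg(effectiveness_definition)
  check_nonneg(cycle_length_months, "cycle_length_months")
  if (cycle_length_months <= 0) stop("`cycle_length_months` must be > 0",
                                     call. = FALSE)
  check_nonneg(horizon_years, "horizon_years")
  if (horizon_years <= 0) stop("`horizon_years` must be > 0", call. = FALSE)
  n_cycles <- horizon_years * 12 / cycle_length_months
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop(sprintf(
      "horizon_years * 12 / cycle_length_months must be an integer cycle count, got %s",
      format(n_cycles)), call. = FALSE)
  check_nonneg(annual_discount_rate, "annual_discount_rate")
  stopifnot(is.logical(half_cycle_correction), length(half_cycle_correction) == 1)
  check_nonneg(general_annual_cost, "general_annual_cost")
  comp <- complication_states()
  cc <- unlist(complication_costs_annual)
  if (!all(comp %in% names(cc)))
    stop("`complication_costs_annual` must name all of: ",
         paste(comp, collapse = ", "), call. = FALSE)
  for (s in comp) check_nonneg(cc[[s]], paste0("complication_costs_annual.", s))
  occ <- unlist(occurrence_probs_annual)
  die <- unlist(death_probs_annual)
  check_prob_vec(occ, "occurrence_probs_annual", comp)
  check_prob_vec(die, "death_probs_annual", comp)
  check_nonneg(complication_risk_rr_controlled, "complication_risk_rr_controlled")
  check_prob(relapse_prob_per_cycle, "relapse_prob_per_cycle")
  check_prob(background_mortality_annual, "background_mortality_annual")
  if (effectiveness_eval_cycles < 1 ||
      abs(effectiveness_eval_cycles - round(effectiveness_eval_cycles)) > 1e-9)
    stop("`effectiveness_eval_cycles` must be a positive integer", call. = FALSE)
  if (effectiveness_eval_cycles > n_cycles)
    stop("`effectiveness_eval_cycles` cannot exceed the number of cycles",
         call. = FALSE)
  strategies <- lapply(strategies, function(s) {
    if (!inherits(s, "a1c_strategy")) s <- do.call(strategy_spec, s)
    s
  })
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  structure(list(
    cycle_length_months = cycle_length_months,
    horizon_years = horizon_years,
    n_cycles = as.integer(round(n_cycles)),
    annual_discount_rate = annual_discount_rate,
    half_cycle_correction = half_cycle_correction,
    target_a1c = target_a1c,
    effectiveness_definition = effectiveness_definition,
    effectiveness_eval_cycles = as.integer(round(effectiveness_eval_cycles)),
    general_annual_cost = general_annual_cost,
    complication_costs_annual = cc[comp],
    occurrence_probs_annual = occ[comp],
    death_probs_annual = die[comp],
    complication_risk_rr_controlled = complication_risk_rr_controlled,
    relapse_prob_per_cycle = relapse_prob_per_cycle,
    background_mortality_annual = background_mortality_annual,
    hospitalization_cost_per_event = isTRUE(hospitalization_cost_per_event),
    strategies = strategies
  ), class = "a1c_model_config")
}

#' Reference model configuration
#'
#' The fully parameterized configuration of the published decision problem:
#' point-of-care A1c testing (`poc`, per-cycle control probability 0.14,
#' cartridge US$8.48, device US$3,976.35) versus centralized laboratory
#' testing (`lab`, control probability 0.0738, test US$2.65), quarterly cycles
#' over 10 years with 4% annual discounting and half-cycle correction.
#'
#' Two quantities the source leaves unstated are calibrated so that the
#' reference run reproduces the published deterministic results (see the
#' methods vignette for the calibration procedure and residuals):
#' `background_mortality_annual = 0.1505924` and
#' `device_tests_lifetime = 78.8576`. The reference effectiveness definition
#' is `assessed_control` with a 4-cycle evaluation window and A1c-result
#' availability of 0.76 (point of care) and 0.36 (laboratory), and the
#' hospitalization cost is charged per admission.
#'
#' @return An object of class `a1c_model_config`.
#' @examples
#' cfg <- reference_config()
#' outcomes <- evaluate_strategies(cfg)
#' sapply(outcomes, `[[`, "discounted_cost")
#' @export
reference_config <- function() {
  model_config(
    cycle_length_months = 3,
    horizon_years = 10,
    annual_discount_rate = 0.04,
    half_cycle_correction = TRUE,
    target_a1c = 7.5,
    effectiveness_definition = "assessed_control",
    effectiveness_eval_cycles = 4,
    general_annual_cost = 1844.00,
    complication_risk_rr_controlled = 0,
    relapse_prob_per_cycle = 0,
    background_mortality_annual = 0.1505924,
    hospitalization_cost_per_event = TRUE,
    strategies = list(
      strategy_spec("poc",
                    control_prob_per_cycle = 0.14,
                    test_cost_per_test = 8.48,
                    device_cost = 3976.35,
                    device_tests_lifetime = 78.8576,
                    tests_per_cycle = 1,
                    a1c_availability = 0.76),
      strategy_spec("lab",
                    control_prob_per_cycle = 0.0738,
                    test_cost_per_test = 2.65,
                    device_cost = 0,
                    device_tests_lifetime = 1,
                    tests_per_cycle = 1,
                    a1c_availability = 0.36)
    )
  )
}

#' @export
print.a1c_model_config <- function(x, ...) {
  cat("Markov cohort model configuration\n")
  cat(sprintf("  %d cycles of %g months over %g years; discount %.1f%%/yr; half-cycle correction: %s\n",
              x$n_cycles, x$cycle_length_months, x$horizon_years,
              100 * x$annual_discount_rate, x$half_cycle_correction))
  cat(sprintf("  effectiveness: %s, window %d cycles; target A1c %.1f%%\n",
              x$effectiveness_definition, x$effectiveness_eval_cycles,
              x$target_a1c))
  cat(sprintf("  general cost %.2f US$/yr; background mortality %.4f/yr\n",
              x$general_annual_cost, x$background_mortality_annual))
  for (s in x$strategies)
    cat(sprintf("  strategy %-4s: control %.4f/cycle, test %.2f US$, device %.2f US$ (amortized over %g tests), availability %.2f\n",
                s$name, s$control_prob_per_cycle, s$test_cost_per_test,
                s$device_cost, s$device_tests_lifetime, s$a1c_availability))
  invisible(x)
}

#' @export
print.a1c_strategy <- function(x, ...) {
  cat(sprintf("Strategy '%s': control %.4f/cycle, test %.2f US$/test\n",
              x$name, x$control_prob_per_cycle, x$test_cost_per_test))
  invisible(x)
}
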