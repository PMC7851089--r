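#' Convert an annual probability to a per-cycle probability
#'
#' Constant-rate conversion: the event hazard is assumed uniform within the
#' year, so `p_cycle = 1 - (1 - p_annual)^(cycle_length_months / 12)`.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycle_length_months Cycle length in months (> 0).
#' @return Per-cycle probability; monotone in `p_annual`.
#' @examples
#' annual_to_cycle_prob(0.1895, 3)  # 0.0512
#' @export
annual_to_cycle_prob <- function(p_annual, cycle_length_months) {
  if (any(cycle_length_months <= 0)) stop("`cycle_length_months` must be > 0",
                                          call. = FALSE)
  if (any(p_annual < 0 | p_annual > 1))
    stop("`p_annual` must be in [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^(cycle_length_months / 12)
}

#' Discount factor at a time point
#'
#' @param annual_rate Annual discount rate (>= 0).
#' @param t Time in years since model entry (>= 0); vectorized.
#' @return `(1 + annual_rate)^(-t)`.
#' @examples
#' discount_factor(0.04, 10)  # 0.6756
#' @export
discount_factor <- function(annual_rate, t) {
  if (any(annual_rate < 0)) stop("`annual_rate` must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-t)
}

# Compose competing per-cycle hazards into one row of transition probabilities.
# Independent hazards combine multiplicatively for the no-event probability;
# the event mass 1 - prod(1 - h) is shared in proportion to the hazards.
compose_competing <- function(hazards, row_name) {
  if (any(hazards < 0 | hazards > 1))
    stop(sprintf("row '%s': hazards must be probabilities in [0, 1]", row_name),
         call. = FALSE)
  if (sum(hazards) > 1 + 1e-12)
    stop(sprintf(
      "row '%s': competing per-cycle probabilities sum to %.4f > 1 and cannot be jointly normalized",
      row_name, sum(hazards)), call. = FALSE)
  stay <- prod(1 - hazards)
  total <- sum(hazards)
  shares <- if (total > 0) hazards / total * (1 - stay) else hazards * 0
  list(shares = shares, stay = stay)
}

#' Build the per-cycle transition matrix for one strategy
#'
#' Uncontrolled patients face competing per-cycle transitions to control
#' (strategy-specific), to each chronic complication, to the one-cycle
#' hospitalization state, and to death from background mortality. Controlled
#' patients face relapse, the complication hazards scaled by
#' `complication_risk_rr_controlled`, and background mortality. Chronic
#' complication states persist and carry their converted annual case-fatality
#' combined with background mortality; hospitalization survivors return to the
#' uncontrolled state after one cycle; `dead` is absorbing.
#'
#' @param config A [model_config()].
#' @param strategy A [strategy_spec()] (or the name of one configured in
#'   `config`).
#' @return A `n_states x n_states` matrix with unit row sums, of class
#'   `a1c_transition_matrix`.
#' @export
build_transition_matrix <- function(config, strategy) {
  stopifnot(inherits(config, "a1c_model_config"))
  if (is.character(strategy)) strategy <- config$strategies[[strategy]]
  stopifnot(inherits(strategy, "a1c_strategy"))
  st <- health_states()
  comp <- complication_states()
  frac <- config$cycle_length_months
  q <- annual_to_cycle_prob(config$occurrence_probs_annual, frac)
  d <- annual_to_cycle_prob(config$death_probs_annual, frac)
  b <- annual_to_cycle_prob(config$background_mortality_annual, frac)

  M <- matrix(0, length(st), length(st), dimnames = list(st, st))

  h_unc <- c(controlled = strategy$control_prob_per_cycle, q, dead = b)
  r <- compose_competing(h_unc, "uncontrolled")
  M["uncontrolled", names(r$shares)] <- r$shares
  M["uncontrolled", "uncontrolled"] <- r$stay

  h_con <- c(uncontrolled = config$relapse_prob_per_cycle,
             q * config$complication_risk_rr_controlled, dead = b)
  r <- compose_competing(h_con, "controlled")
  M["controlled", names(r$shares)] <- r$shares
  M["controlled", "controlled"] <- r$stay

  for (s in setdiff(comp, "hospitalization")) {
    dd <- 1 - (1 - d[[s]]) * (1 - b)  # case fatality and background compete
    M[s, "dead"] <- dd
    M[s, s] <- 1 - dd
  }
  dh <- 1 - (1 - d[["hospitalization"]]) * (1 - b)
  M["hospitalization", "dead"] <- dh
  M["hospitalization", "uncontrolled"] <- 1 - dh
  M["dead", "dead"] <- 1

  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))
  class(M) <- c("a1c_transition_matrix", class(M))
  M
}

#' Run the Markov cohort simulation
#'
#' The whole cohort enters in the `uncontrolled` state; occupancy is propagated
#' by left-multiplication with the transition matrix for
#' `horizon_years * 12 / cycle_length_months` cycles.
#'
#' @param matrix Transition matrix from [build_transition_matrix()].
#' @param config The [model_config()] used to build it.
#' @return An object of class `a1c_cohort_trace`: list with `occupancy`
#'   (`(n_cycles + 1) x n_states` matrix, rows sum to 1) and `cycle_times`
#'   (years since entry at each row).
#' @export
run_cohort <- function(matrix, config) {
  stopifnot(inherits(config, "a1c_model_config"))
  st <- health_states()
  stopifnot(is.matrix(matrix), all(dim(matrix) == length(st)))
  K <- config$n_cycles
  occ <- base::matrix(0, K + 1, length(st), dimnames = list(NULL, st))
  occ[1, "uncontrolled"] <- 1
  M <- unclass(matrix)
  for (k in seq_len(K)) occ[k + 1, ] <- occ[k, ] %*% M
  structure(list(
    occupancy = occ,
    cycle_times = (0:K) * config$cycle_length_months / 12
  ), class = "a1c_cohort_trace")
}

# Per-cycle cost carried by one full-time occupant of each state, including
# testing of alive patients. Hospitalization is optionally charged per event.
state_cycle_costs <- function(config, strategy) {
  st <- health_states()
  frac <- config$cycle_length_months / 12
  costs <- stats::setNames(numeric(length(st)), st)
  alive <- setdiff(st, "dead")
  costs[alive] <- config$general_annual_cost * frac
  for (s in complication_states())
    costs[s] <- costs[s] + config$complication_costs_annual[[s]] * frac
  if (config$hospitalization_cost_per_event)
    costs["hospitalization"] <- config$general_annual_cost * frac +
      config$complication_costs_annual[["hospitalization"]]
  test_cost <- strategy$tests_per_cycle *
    (strategy$test_cost_per_test +
       strategy$device_cost / strategy$device_tests_lifetime)
  costs[alive] <- costs[alive] + test_cost
  costs
}

# First-passage probability of having entered `controlled` by cycle k,
# computed on a modified chain in which `controlled` is absorbing.
first_passage_controlled <- function(matrix, config, k) {
  M <- unclass(matrix)
  M["controlled", ] <- 0
  M["controlled", "controlled"] <- 1
  occ <- stats::setNames(numeric(ncol(M)), colnames(M))
  occ["uncontrolled"] <- 1
  for (i in seq_len(k)) occ <- drop(occ %*% M)
  unname(occ["controlled"])
}

#' Accrue discounted cost and effectiveness from a cohort trace
#'
#' Costs accrue per cycle as occupancy times per-cycle state costs (general
#' diabetes care for every alive patient, complication costs on top, testing
#' and amortized device cost per alive patient), discounted at the cycle
#' boundary times. With `half_cycle_correction` the per-cycle accruals are
#' combined trapezoidally (mean of adjacent boundary rows), otherwise the
#' start-of-cycle convention is used. Effectiveness follows
#' `config$effectiveness_definition` (see [model_config()]).
#'
#' @param trace Trace from [run_cohort()] under the same `config`.
#' @param config The [model_config()].
#' @param strategy The [strategy_spec()] the trace was run for.
#' @return An object of class `a1c_strategy_outcome`: list with `strategy`,
#'   `discounted_cost` (US$/patient), `effectiveness` (probability) and
#'   `trace`.
#' @export
accrue_outcomes <- function(trace, config, strategy) {
  stopifnot(inherits(trace, "a1c_cohort_trace"),
            inherits(config, "a1c_model_config"))
  if (is.character(strategy)) strategy <- config$strategies[[strategy]]
  stopifnot(inherits(strategy, "a1c_strategy"))
  occ <- trace$occupancy
  if (nrow(occ) != config$n_cycles + 1)
    stop("trace and config disagree on the number of cycles", call. = FALSE)
  costs <- state_cycle_costs(config, strategy)
  disc <- discount_factor(config$annual_discount_rate, trace$cycle_times)
  boundary <- drop(occ %*% costs) * disc
  K <- config$n_cycles
  discounted_cost <- if (config$half_cycle_correction) {
    sum((boundary[1:K] + boundary[2:(K + 1)]) / 2)
  } else {
    sum(boundary[1:K])
  }

  k_eval <- config$effectiveness_eval_cycles
  effectiveness <- switch(
    config$effectiveness_definition,
    assessed_control = strategy$a1c_availability *
      (1 - (1 - strategy$control_prob_per_cycle)^k_eval),
    cumulative_ever = {
      M <- build_transition_matrix(config, strategy)
      first_passage_controlled(M, config, k_eval)
    },
    at_eval_point = unname(occ[k_eval + 1, "controlled"]),
    discounted_time_in_control = {
      frac <- config$cycle_length_months / 12
      con <- occ[, "controlled"] * disc
      tot <- disc
      num <- if (config$half_cycle_correction)
        sum((con[1:K] + con[2:(K + 1)]) / 2) else sum(con[1:K])
      den <- if (config$half_cycle_correction)
        sum((tot[1:K] + tot[2:(K + 1)]) / 2) else sum(tot[1:K])
      num / den
    }
  )
  structure(list(
    strategy = strategy$name,
    discounted_cost = discounted_cost,
    effectiveness = effectiveness,
    trace = trace
  ), class = "a1c_strategy_outcome")
}

#' Evaluate all configured strategies
#'
#' Runs [build_transition_matrix()], [run_cohort()] and [accrue_outcomes()]
#' for each strategy in the configuration.
#'
#' @param config A [model_config()] with at least one strategy.
#' @return Named list of `a1c_strategy_outcome` objects.
#' @examples
#' outcomes <- evaluate_strategies(reference_config())
#' outcomes$poc$discounted_cost
#' @export
evaluate_strategies <- function(config) {
  stopifnot(inherits(config, "a1c_model_config"))
  if (length(config$strategies) == 0)
    stop("no strategies configured", call. = FALSE)
  out <- lapply(config$strategies, function(s) {
    M <- build_transition_matrix(config, s)
    tr <- run_cohort(M, config)
    accrue_outcomes(tr, config, s)
  })
  names(out) <- names(config$strategies)
  out
}

#' @export
print.a1c_strategy_outcome <- function(x, ...) {
  cat(sprintf("Strategy '%s': discounted cost %.2f US$/patient, effectiveness %.4f\n",
              x$strategy, x$discounted_cost, x$effectiveness))
  invisible(x)
}

#' Export a cohort trace as a long data frame
#'
#' @param trace An `a1c_cohort_trace`.
#' @return Data frame with columns `cycle`, `time_years`, `state`, `occupancy`.
#' @export
trace_as_df <- function(trace) {
  stopifnot(inherits(trace, "a1c_cohort_trace"))
  occ <- trace$occupancy
  data.frame(
    cycle = rep(seq_len(nrow(occ)) - 1L, times = ncol(occ)),
    time_years = rep(trace$cycle_times, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ),
    stringsAsFactors = FALSE
  )
}
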