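# Builders for stripped-down configurations used across tests.

# A config in which only the named hazards are non-zero; defaults give an
# inert chain (no transitions at all except those requested).
bare_config <- function(p_ctrl = 0, occ = 0, death = 0, bg = 0,
                        relapse = 0, rr = 0,
                        general = 0, test_cost = 0,
                        comp_costs = 0,
                        discount = 0, horizon = 10,
                        half_cycle = TRUE, eval_cycles = 2,
                        effectiveness = "cumulative_ever",
                        hosp_per_event = FALSE,
                        availability = 1) {
  comp <- c("cvd", "retinopathy", "nephropathy", "hospitalization",
            "diabetic_foot")
  rep_named <- function(x) {
    if (length(x) == 1) x <- rep(x, length(comp))
    stats::setNames(x, comp)
  }
  model_config(
    cycle_length_months = 3,
    horizon_years = horizon,
    annual_discount_rate = discount,
    half_cycle_correction = half_cycle,
    effectiveness_definition = effectiveness,
    effectiveness_eval_cycles = eval_cycles,
    general_annual_cost = general,
    complication_costs_annual = rep_named(comp_costs),
    occurrence_probs_annual = rep_named(occ),
    death_probs_annual = rep_named(death),
    complication_risk_rr_controlled = rr,
    relapse_prob_per_cycle = relapse,
    background_mortality_annual = bg,
    hospitalization_cost_per_event = hosp_per_event,
    strategies = list(
      strategy_spec("poc", control_prob_per_cycle = p_ctrl,
                    test_cost_per_test = test_cost,
                    a1c_availability = availability),
      strategy_spec("lab", control_prob_per_cycle = p_ctrl,
                    test_cost_per_test = test_cost,
                    a1c_availability = availability)
    )
  )
}

# Fabricate a strategy outcome without running the engine.
fake_outcome <- function(name, cost, eff) {
  structure(list(strategy = name, discounted_cost = cost,
                 effectiveness = eff, trace = NULL),
            class = "a1c_strategy_outcome")
}
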