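# Reference parameterization: point-of-care vs. centralized laboratory A1c
# testing for type 2 diabetes monitoring in Brazilian primary care.
# Costs in 2020 US$; probabilities per patient-year unless noted.
# background_mortality_annual and the poc device_tests_lifetime are
# calibrated constants (see the methods vignette).
model:
  cycle_length_months: 3
  horizon_years: 10
  annual_discount_rate: 0.04
  half_cycle_correction: true
  target_a1c: 7.5
  effectiveness_definition: assessed_control
  effectiveness_eval_cycles: 4
  general_annual_cost: 1844.00
  complication_costs_annual:
    cvd: 1529.00
    retinopathy: 621.00
    nephropathy: 1602.00
    hospitalization: 3917.00
    diabetic_foot: 166.2666666666667   # mean of 162.10, 112.90, 223.80
  occurrence_probs_annual:
    cvd: 0.129
    retinopathy: 0.1340
    nephropathy: 0.1680
    hospitalization: 0.1895
    diabetic_foot: 0.0310
  death_probs_annual:
    cvd: 0.2840
    retinopathy: 0.0000
    nephropathy: 0.0381
    hospitalization: 0.0617
    diabetic_foot: 0.0740
  complication_risk_rr_controlled: 0.0
  relapse_prob_per_cycle: 0.0
  background_mortality_annual: 0.1505924
  hospitalization_cost_per_event: true
strategies:
  - name: poc
    control_prob_per_cycle: 0.14
    test_cost_per_test: 8.48
    device_cost: 3976.35
    device_tests_lifetime: 78.8576
    tests_per_cycle: 1
    a1c_availability: 0.76
  - name: lab
    control_prob_per_cycle: 0.0738
    test_cost_per_test: 2.65
    device_cost: 0.0
    device_tests_lifetime: 1
    tests_per_cycle: 1
    a1c_availability: 0.36
cohort:
  n_poc: 288
  n_lab: 1102
  p_a1c_available_poc: 0.76
  p_a1c_available_lab: 0.36
  p_male_poc: 0.37
  p_male_lab: 0.234
  age_mean_poc: 61.9
  age_mean_lab: 56.8
  age_sd_poc: 15.4421
  age_sd_lab: 18.2575
  a1c_median_poc: 7.8
  a1c_iqr_poc: [6.7, 9.5]
  a1c_median_lab: 7.9
  a1c_iqr_lab: [6.8, 10.6]
  p_hypertension_poc: 0.917
  p_hypertension_lab: 0.935
  control_prob_per_cycle_poc: 0.14
  control_prob_per_cycle_lab: 0.0738
  followup_cycles: 6
  seed: 1
psa:
  n_trials: 1000
  dispersion: 0.2
  seed: 1
tornado:
  wtp: 2000
  range_fraction: 0.2
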