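test_that("annual-to-cycle probability conversion matches the closed form", {
  expect_identical(annual_to_cycle_prob(0, 3), 0)
  # frozen from 1 - (1 - p)^(3/12) for the hospitalization and diabetic-foot
  # annual occurrence probabilities
  expect_equal(annual_to_cycle_prob(0.1895, 3), 0.0511703341, tolerance = 1e-8)
  expect_equal(annual_to_cycle_prob(0.0310, 3), 0.0078417585, tolerance = 1e-8)
  expect_equal(annual_to_cycle_prob(1, 3), 1)
  # monotone in the annual probability
  p <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(annual_to_cycle_prob(p, 3)) > 0))
  expect_error(annual_to_cycle_prob(0.5, 0), "cycle_length_months")
  expect_error(annual_to_cycle_prob(1.2, 3), "0, 1")
})

test_that("discount factor matches the closed form and rejects bad input", {
  expect_identical(discount_factor(0.04, 0), 1)
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  expect_equal(discount_factor(0.04, 10), 1.04^-10)
  t <- seq(0, 10, by = 0.25)
  expect_true(all(diff(discount_factor(0.04, t)) < 0))
  expect_error(discount_factor(0.04, -1), ">= 0")
})

test_that("transition matrix rows sum to one and degenerate cases are identity-like", {
  cfg <- reference_config()
  for (s in names(cfg$strategies)) {
    M <- build_transition_matrix(cfg, s)
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
    expect_identical(unname(M["dead", "dead"]), 1)
  }
  # POC strategy moves uncontrolled patients to control with the configured
  # per-cycle rate, rescaled only by the competing-hazard composition
  M <- build_transition_matrix(cfg, "poc")
  h <- c(0.14,
         annual_to_cycle_prob(cfg$occurrence_probs_annual, 3),
         annual_to_cycle_prob(cfg$background_mortality_annual, 3))
  expect_equal(unname(M["uncontrolled", "controlled"]),
               0.14 / sum(h) * (1 - prod(1 - h)), tolerance = 1e-12)

  # all hazards zero: every state persists, except that the one-cycle
  # hospitalization state still discharges to uncontrolled
  M0 <- build_transition_matrix(bare_config(), "poc")
  expected <- diag(8)
  dimnames(expected) <- dimnames(M0)
  expected["hospitalization", "hospitalization"] <- 0
  expected["hospitalization", "uncontrolled"] <- 1
  expect_equal(unclass(M0), expected, ignore_attr = TRUE)

  # jointly unnormalizable hazards are refused, naming the row
  bad <- bare_config(p_ctrl = 0.9, occ = 0.9)
  expect_error(build_transition_matrix(bad, "poc"), "uncontrolled")
})

test_that("cohort trace follows closed-form geometric chains", {
  # 2-state: uncontrolled -> controlled with p = 0.5, controlled absorbing
  cfg <- bare_config(p_ctrl = 0.5)
  tr <- run_cohort(build_transition_matrix(cfg, "poc"), cfg)
  k <- 0:cfg$n_cycles
  expect_equal(unname(tr$occupancy[, "uncontrolled"]), 0.5^k,
               tolerance = 1e-10)
  expect_equal(unname(tr$occupancy[, "controlled"]), 1 - 0.5^k,
               tolerance = 1e-10)

  # 3-state: control competes with a single complication hazard; the
  # closed form is derived here from the composition rule, independently
  # of the engine
  p <- 0.2
  occ_ann <- c(cvd = 0.3, retinopathy = 0, nephropathy = 0,
               hospitalization = 0, diabetic_foot = 0)
  cfg3 <- bare_config(p_ctrl = p, occ = occ_ann)
  q <- 1 - 0.7^0.25
  stay <- (1 - p) * (1 - q)
  share_con <- p / (p + q) * (1 - stay)
  share_cvd <- q / (p + q) * (1 - stay)
  tr3 <- run_cohort(build_transition_matrix(cfg3, "poc"), cfg3)
  geom_sum <- c(0, cumsum(stay^(0:(cfg3$n_cycles - 1))))
  expect_equal(unname(tr3$occupancy[, "uncontrolled"]), stay^(0:40),
               tolerance = 1e-10)
  expect_equal(unname(tr3$occupancy[, "controlled"]), share_con * geom_sum,
               tolerance = 1e-10)
  expect_equal(unname(tr3$occupancy[, "cvd"]), share_cvd * geom_sum,
               tolerance = 1e-10)

  # identity matrix: the cohort never leaves the entry state
  cfg0 <- bare_config()
  tr0 <- run_cohort(build_transition_matrix(cfg0, "poc"), cfg0)
  expect_true(all(tr0$occupancy[, "uncontrolled"] == 1))
})

test_that("cohort mass is conserved and death occupancy is monotone", {
  set.seed(421)
  for (i in 1:15) {
    cfg <- bare_config(
      p_ctrl = runif(1, 0, 0.3),
      occ = runif(5, 0, 0.25),
      death = runif(5, 0, 0.3),
      bg = runif(1, 0, 0.2),
      relapse = runif(1, 0, 0.3),
      rr = runif(1, 0, 1))
    tr <- run_cohort(build_transition_matrix(cfg, "poc"), cfg)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
  }
})

test_that("cost accrual matches hand-built oracles", {
  # zero costs everywhere -> zero discounted cost
  cfg <- reference_config()
  cfg$general_annual_cost <- 0
  cfg$complication_costs_annual[] <- 0
  for (nm in names(cfg$strategies)) {
    cfg$strategies[[nm]]$test_cost_per_test <- 0
    cfg$strategies[[nm]]$device_cost <- 0
  }
  out <- evaluate_strategies(cfg)
  expect_equal(out$poc$discounted_cost, 0)

  # one absorbing state with annual cost C, no death, no discounting,
  # 10 years -> exactly 10 C
  cfgC <- bare_config(general = 1844, discount = 0)
  outC <- evaluate_strategies(cfgC)
  expect_equal(outC$poc$discounted_cost, 10 * 1844, tolerance = 1e-10)

  # independent re-implementation of the accrual rule for the full
  # reference configuration
  cfg <- reference_config()
  strat <- cfg$strategies$poc
  tr <- run_cohort(build_transition_matrix(cfg, strat), cfg)
  frac <- 1 / 4
  st <- colnames(tr$occupancy)
  cost_vec <- setNames(numeric(8), st)
  alive <- setdiff(st, "dead")
  cost_vec[alive] <- 1844 * frac + strat$test_cost_per_test +
    strat$device_cost / strat$device_tests_lifetime
  for (s in c("cvd", "retinopathy", "nephropathy", "diabetic_foot"))
    cost_vec[s] <- cost_vec[s] + cfg$complication_costs_annual[[s]] * frac
  cost_vec["hospitalization"] <- cost_vec["hospitalization"] + 3917  # per event
  boundary <- drop(tr$occupancy %*% cost_vec) * 1.04^(-tr$cycle_times)
  oracle <- sum((boundary[1:40] + boundary[2:41]) / 2)
  out <- accrue_outcomes(tr, cfg, strat)
  expect_equal(out$discounted_cost, oracle, tolerance = 1e-10)

  # half-cycle corrected cost is the mean of the start- and end-of-cycle
  # conventions, hence lies between them
  start_conv <- sum(boundary[1:40])
  end_conv <- sum(boundary[2:41])
  expect_equal(out$discounted_cost, (start_conv + end_conv) / 2,
               tolerance = 1e-10)
  expect_true(out$discounted_cost < start_conv)
  expect_true(out$discounted_cost > end_conv)
})

test_that("all four effectiveness definitions behave and agree where they should", {
  # no competing risks, no relapse: cumulative_ever equals at_eval_point
  # equals the geometric closed form
  for (defn in c("cumulative_ever", "at_eval_point")) {
    cfg <- bare_config(p_ctrl = 0.14, eval_cycles = 2, effectiveness = defn)
    out <- evaluate_strategies(cfg)
    expect_equal(out$poc$effectiveness, 1 - 0.86^2, tolerance = 1e-12)
  }
  # assessed_control multiplies by availability
  cfg <- bare_config(p_ctrl = 0.14, eval_cycles = 4,
                     effectiveness = "assessed_control", availability = 0.76)
  out <- evaluate_strategies(cfg)
  expect_equal(out$poc$effectiveness, 0.76 * (1 - 0.86^4), tolerance = 1e-12)
  # with relapse, cumulative_ever counts first passage and therefore exceeds
  # point occupancy
  cfg_e <- bare_config(p_ctrl = 0.3, relapse = 0.4, eval_cycles = 8,
                       effectiveness = "cumulative_ever")
  cfg_p <- bare_config(p_ctrl = 0.3, relapse = 0.4, eval_cycles = 8,
                       effectiveness = "at_eval_point")
  expect_gt(evaluate_strategies(cfg_e)$poc$effectiveness,
            evaluate_strategies(cfg_p)$poc$effectiveness)
  # discounted time in control is a fraction of the horizon
  cfg_t <- bare_config(p_ctrl = 0.3, effectiveness = "discounted_time_in_control")
  eff_t <- evaluate_strategies(cfg_t)$poc$effectiveness
  expect_gt(eff_t, 0)
  expect_lt(eff_t, 1)
})

test_that("raising the control rate never hurts effectiveness or raises complication costs", {
  grid <- seq(0.02, 0.3, by = 0.04)
  for (defn in c("cumulative_ever", "at_eval_point", "assessed_control",
                 "discounted_time_in_control")) {
    effs <- vapply(grid, function(p) {
      cfg <- bare_config(p_ctrl = p, occ = c(0.1, 0.1, 0.1, 0.1, 0.05),
                         death = 0.1, eval_cycles = 4, effectiveness = defn,
                         availability = 0.8)
      evaluate_strategies(cfg)$poc$effectiveness
    }, numeric(1))
    expect_true(all(diff(effs) >= -1e-12), info = defn)
  }
  comp_costs <- vapply(grid, function(p) {
    cfg <- bare_config(p_ctrl = p, occ = c(0.1, 0.1, 0.1, 0.1, 0.05),
                       death = 0.1, comp_costs = 1000)
    evaluate_strategies(cfg)$poc$discounted_cost
  }, numeric(1))
  expect_true(all(diff(comp_costs) <= 1e-9))
})

test_that("discounting at 4% never exceeds the undiscounted cost", {
  cfg0 <- reference_config()
  cfg0$annual_discount_rate <- 0
  out0 <- evaluate_strategies(cfg0)
  out4 <- evaluate_strategies(reference_config())
  for (nm in c("poc", "lab"))
    expect_gt(out0[[nm]]$discounted_cost, out4[[nm]]$discounted_cost)
})

test_that("identical strategies produce bit-identical outcomes", {
  cfg <- reference_config()
  cfg$strategies$lab <- cfg$strategies$poc
  cfg$strategies$lab$name <- "lab"
  out <- evaluate_strategies(cfg)
  expect_identical(out$poc$discounted_cost, out$lab$discounted_cost)
  expect_identical(out$poc$effectiveness, out$lab$effectiveness)
})

test_that("trace exports as a tidy data frame", {
  cfg <- reference_config()
  out <- evaluate_strategies(cfg)
  df <- trace_as_df(out$poc$trace)
  expect_identical(names(df), c("cycle", "time_years", "state", "occupancy"))
  expect_identical(nrow(df), 41L * 8L)
  expect_equal(sum(df$occupancy), 41, tolerance = 1e-8)
})
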