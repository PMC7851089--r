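test_that("generated cohorts have exact group sizes and are seed-reproducible", {
  coh <- generate_cohort(cohort_config(seed = 42))
  tab <- table(coh$patients$group)
  expect_identical(as.integer(tab[["poc"]]), 288L)
  expect_identical(as.integer(tab[["lab"]]), 1102L)
  coh2 <- generate_cohort(cohort_config(seed = 42))
  expect_identical(coh$patients, coh2$patients)
  coh3 <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(coh$patients, coh3$patients))
})

test_that("patient records respect their invariants", {
  coh <- generate_cohort(cohort_config(seed = 1))
  p <- coh$patients
  a1c <- p$baseline_a1c[!is.na(p$baseline_a1c)]
  expect_true(all(a1c > 0 & a1c < 20))
  ctrl <- p$controlled_at_cycle[!is.na(p$controlled_at_cycle)]
  expect_true(all(ctrl >= 1 & ctrl <= coh$config$followup_cycles))
  # patients without an available A1c result never register control
  expect_true(all(is.na(p$controlled_at_cycle[is.na(p$baseline_a1c)])))
  expect_true(all(p$sex %in% c("male", "female")))
})

test_that("zero control probability yields no controlled patients", {
  cc <- cohort_config(control_prob_per_cycle_poc = 0,
                      control_prob_per_cycle_lab = 0, seed = 5)
  coh <- generate_cohort(cc)
  expect_true(all(is.na(coh$patients$controlled_at_cycle)))
})

test_that("ever-controlled fraction converges to the geometric closed form", {
  # 1 - (1 - p)^k with p = 0.14 over 6 cycles, universal availability
  cc <- cohort_config(n_poc = 10000, n_lab = 2,
                      p_a1c_available_poc = 1,
                      control_prob_per_cycle_poc = 0.14, seed = 31)
  coh <- generate_cohort(cc)
  poc <- coh$patients[coh$patients$group == "poc", ]
  frac <- mean(!is.na(poc$controlled_at_cycle))
  expected <- 1 - 0.86^6
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("the control-rate estimator is exact in degenerate cohorts and recovers parameters", {
  # every patient controls at the first cycle -> p_hat = 1
  cc <- cohort_config(n_poc = 50, n_lab = 2, p_a1c_available_poc = 1,
                      control_prob_per_cycle_poc = 1, seed = 2)
  coh <- generate_cohort(cc)
  r <- estimate_control_rate(coh, "poc")
  expect_identical(r$p_hat, 1)
  expect_identical(r$n_used, 50L)
  # large-sample recovery of both generating rates inside the 95% CI
  cc <- cohort_config(n_poc = 10000, n_lab = 10000,
                      p_a1c_available_poc = 1, p_a1c_available_lab = 1,
                      control_prob_per_cycle_poc = 0.14,
                      control_prob_per_cycle_lab = 0.0738, seed = 8)
  coh <- generate_cohort(cc)
  for (spec in list(c("poc", 0.14), c("lab", 0.0738))) {
    r <- estimate_control_rate(coh, spec[1])
    p <- as.numeric(spec[2])
    expect_true(r$ci_low <= p && p <= r$ci_high)
    expect_true(r$ci_low <= r$p_hat && r$p_hat <= r$ci_high)
  }
  # empty assessable group is an error
  cc0 <- cohort_config(p_a1c_available_poc = 0, seed = 1)
  expect_error(estimate_control_rate(generate_cohort(cc0), "poc"),
               "no assessable")
})

test_that("baseline summary matches the configured marginals within sampling error", {
  coh <- generate_cohort(cohort_config(seed = 19))
  s <- summarize_baseline(coh)
  poc <- s[s$group == "poc", ]
  lab <- s[s$group == "lab", ]
  se_avail_poc <- sqrt(0.76 * 0.24 / 288)
  se_avail_lab <- sqrt(0.36 * 0.64 / 1102)
  expect_lt(abs(poc$frac_a1c_available - 0.76), 3 * se_avail_poc)
  expect_lt(abs(lab$frac_a1c_available - 0.36), 3 * se_avail_lab)
  expect_lt(abs(poc$a1c_median - 7.8), 0.2)
  expect_lt(abs(lab$a1c_median - 7.9), 0.2)
  expect_lt(abs(poc$age_mean - 61.9), 3 * 15.45 / sqrt(288))
  expect_lt(abs(lab$age_mean - 56.8), 3 * 18.26 / sqrt(1102))
  expect_lt(abs(poc$frac_hypertension - 0.917), 3 * sqrt(0.917 * 0.083 / 288))
})

test_that("a single-patient cohort summarizes without error", {
  cc <- cohort_config(n_poc = 1, n_lab = 1, seed = 3)
  s <- summarize_baseline(generate_cohort(cc))
  expect_identical(nrow(s), 2L)
  expect_true(all(s$n == 1))
})

test_that("the log-normal fit pins the median and minimizes the IQR error", {
  z <- qnorm(0.75)
  for (target in list(list(m = 7.8, iqr = c(6.7, 9.5)),
                      list(m = 7.9, iqr = c(6.8, 10.6)))) {
    fit <- fit_lognormal_iqr(target$m, target$iqr)
    expect_equal(exp(fit$meanlog), target$m, tolerance = 1e-12)
    expect_true(fit$q25 < target$m && target$m < fit$q75)
    # grid-search oracle for the least-squares spread
    grid <- seq(0.01, 1, by = 5e-4)
    sse <- (exp(fit$meanlog - z * grid) - target$iqr[1])^2 +
      (exp(fit$meanlog + z * grid) - target$iqr[2])^2
    expect_lt(abs(fit$sdlog - grid[which.min(sse)]), 1e-3)
  }
})

test_that("cohort CSV round-trips with the documented header", {
  coh <- generate_cohort(cohort_config(seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  header <- readLines(path, n = 1)
  expect_identical(header,
                   "id,group,sex,age,hypertension,baseline_a1c,controlled_at_cycle")
  back <- read_cohort_csv(path, coh$config)
  expect_identical(back$patients$id, coh$patients$id)
  expect_identical(back$patients$controlled_at_cycle,
                   coh$patients$controlled_at_cycle)
  expect_equal(back$patients$age, coh$patients$age, tolerance = 1e-10)
  expect_equal(back$patients$baseline_a1c, coh$patients$baseline_a1c,
               tolerance = 1e-10)
  # an estimator run on the re-read cohort gives identical counts
  r1 <- estimate_control_rate(coh, "poc")
  r2 <- estimate_control_rate(back, "poc")
  expect_identical(r1$events, r2$events)
  expect_identical(r1$trials, r2$trials)
})

test_that("invalid cohort configurations are rejected with the offending field", {
  expect_error(cohort_config(p_male_poc = 1.3), "p_male_poc")
  expect_error(cohort_config(n_poc = 0), "n_poc")
  expect_error(cohort_config(a1c_median_poc = 6.5), "a1c_iqr_poc")
  expect_error(cohort_config(followup_cycles = 0), "followup_cycles")
})
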