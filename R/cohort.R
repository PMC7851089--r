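#' Configuration of the synthetic patient cohort
#'
#' Defines the two monitoring groups (point-of-care device unit vs. units
#' served by the central laboratory) by size, A1c-result availability, sex
#' mix, age distribution, baseline A1c distribution (median and interquartile
#' range of a right-skewed marker), hypertension prevalence, per-cycle
#' glycemic-control probabilities and follow-up length.
#'
#' Age dispersion defaults are standard deviations reconstructed from the
#' published standard errors of the mean (0.91 and 0.55 years) times the
#' square root of the group sizes.
#'
#' @param n_poc,n_lab Group sizes (defaults 288 and 1102).
#' @param p_a1c_available_poc,p_a1c_available_lab Probability that a patient
#'   has an A1c result available (defaults 0.76 and 0.36).
#' @param p_male_poc,p_male_lab Probability of male sex (defaults 0.37 and
#'   0.234).
#' @param age_mean_poc,age_mean_lab Mean ages in years (defaults 61.9, 56.8).
#' @param age_sd_poc,age_sd_lab Age standard deviations in years.
#' @param a1c_median_poc,a1c_median_lab Baseline A1c medians in percent
#'   (defaults 7.8, 7.9).
#' @param a1c_iqr_poc,a1c_iqr_lab Baseline A1c interquartile ranges,
#'   `c(lower, upper)` (defaults 6.7-9.5 and 6.8-10.6).
#' @param p_hypertension_poc,p_hypertension_lab Hypertension prevalence
#'   (defaults 0.917 and 0.935).
#' @param control_prob_per_cycle_poc,control_prob_per_cycle_lab Per-cycle
#'   probability that an assessable uncontrolled patient reaches the A1c
#'   target (defaults 0.14 and 0.0738).
#' @param followup_cycles Follow-up length in 3-month cycles (default 6, i.e.
#'   18 months).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `a1c_cohort_config`.
#' @export
cohort_config <- function(n_poc = 288, n_lab = 1102,
                          p_a1c_available_poc = 0.76,
                          p_a1c_available_lab = 0.36,
                          p_male_poc = 0.37, p_male_lab = 0.234,
                          age_mean_poc = 61.9, age_mean_lab = 56.8,
                          age_sd_poc = 0.91 * sqrt(288),
                          age_sd_lab = 0.55 * sqrt(1102),
                          a1c_median_poc = 7.8, a1c_iqr_poc = c(6.7, 9.5),
                          a1c_median_lab = 7.9, a1c_iqr_lab = c(6.8, 10.6),
                          p_hypertension_poc = 0.917,
                          p_hypertension_lab = 0.935,
                          control_prob_per_cycle_poc = 0.14,
                          control_prob_per_cycle_lab = 0.0738,
                          followup_cycles = 6,
                          seed = 1L) {
  for (nm in c("n_poc", "n_lab")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 ||
        abs(v - round(v)) > 1e-9)
      stop(sprintf("`%s` must be a positive integer count", nm), call. = FALSE)
  }
  for (nm in c("p_a1c_available_poc", "p_a1c_available_lab", "p_male_poc",
               "p_male_lab", "p_hypertension_poc", "p_hypertension_lab",
               "control_prob_per_cycle_poc", "control_prob_per_cycle_lab"))
    check_prob(get(nm), nm)
  for (grp in c("poc", "lab")) {
    med <- get(paste0("a1c_median_", grp))
    iqr <- get(paste0("a1c_iqr_", grp))
    if (length(iqr) != 2 || !(iqr[1] < med && med < iqr[2]))
      stop(sprintf("a1c_iqr_%s must straddle the median: lower < median < upper",
                   grp), call. = FALSE)
  }
  if (followup_cycles < 1 || abs(followup_cycles - round(followup_cycles)) > 1e-9)
    stop("`followup_cycles` must be a positive integer", call. = FALSE)
  structure(list(
    n_poc = as.integer(n_poc), n_lab = as.integer(n_lab),
    p_a1c_available_poc = p_a1c_available_poc,
    p_a1c_available_lab = p_a1c_available_lab,
    p_male_poc = p_male_poc, p_male_lab = p_male_lab,
    age_mean_poc = age_mean_poc, age_mean_lab = age_mean_lab,
    age_sd_poc = age_sd_poc, age_sd_lab = age_sd_lab,
    a1c_median_poc = a1c_median_poc, a1c_iqr_poc = a1c_iqr_poc,
    a1c_median_lab = a1c_median_lab, a1c_iqr_lab = a1c_iqr_lab,
    p_hypertension_poc = p_hypertension_poc,
    p_hypertension_lab = p_hypertension_lab,
    control_prob_per_cycle_poc = control_prob_per_cycle_poc,
    control_prob_per_cycle_lab = control_prob_per_cycle_lab,
    followup_cycles = as.integer(followup_cycles),
    seed = as.integer(seed)
  ), class = "a1c_cohort_config")
}

#' Fit a log-normal distribution to a median and interquartile range
#'
#' The log-scale location is fixed by the median (`mu = log(median)`); the
#' log-scale spread is chosen to minimize the squared error between the
#' implied and the target quartiles. A1c is strictly positive and
#' right-skewed, which the log-normal captures.
#'
#' @param median Target median (> 0).
#' @param iqr Target `c(q25, q75)`.
#' @return List with `meanlog`, `sdlog` and the fitted quartiles.
#' @export
fit_lognormal_iqr <- function(median, iqr) {
  stopifnot(median > 0, length(iqr) == 2, iqr[1] < median, median < iqr[2])
  mu <- log(median)
  z <- stats::qnorm(0.75)
  sse <- function(sigma)
    (exp(mu - z * sigma) - iqr[1])^2 + (exp(mu + z * sigma) - iqr[2])^2
  sigma <- stats::optimize(sse, c(1e-6, 2))$minimum
  list(meanlog = mu, sdlog = sigma,
       q25 = exp(mu - z * sigma), q75 = exp(mu + z * sigma))
}

generate_group <- function(cfg, group) {
  g <- function(field) cfg[[paste0(field, "_", group)]]
  n <- g("n")
  avail <- stats::runif(n) < g("p_a1c_available")
  sex <- ifelse(stats::runif(n) < g("p_male"), "male", "female")
  age <- stats::rnorm(n, g("age_mean"), g("age_sd"))
  hyp <- stats::runif(n) < g("p_hypertension")
  fit <- fit_lognormal_iqr(g("a1c_median"), g("a1c_iqr"))
  a1c <- stats::rlnorm(n, fit$meanlog, fit$sdlog)
  # A1c is bounded in practice; resample the rare draws outside (0, 20)
  while (any(bad <- a1c <= 0 | a1c >= 20))
    a1c[bad] <- stats::rlnorm(sum(bad), fit$meanlog, fit$sdlog)
  a1c[!avail] <- NA_real_
  # first cycle at which the target is reached: geometric per-cycle hazard,
  # only assessable patients (with an available result) can register control
  p <- g("control_prob_per_cycle")
  ctrl <- rep(NA_integer_, n)
  if (p > 0) {
    first <- stats::rgeom(n, p) + 1L
    ok <- avail & first <= cfg$followup_cycles
    ctrl[ok] <- first[ok]
  }
  data.frame(
    id = paste0(group, "_", seq_len(n)),
    group = group,
    sex = sex,
    age = age,
    hypertension = hyp,
    baseline_a1c = a1c,
    controlled_at_cycle = ctrl,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws patient-level records for the two monitoring groups from the
#' configured marginal distributions: Bernoulli availability, sex and
#' hypertension; normal ages; log-normal baseline A1c matched to the
#' configured median and interquartile range; and a constant per-cycle
#' control hazard over the follow-up window, absorbing on first success.
#' Patients without an available A1c result never register control. All draws
#' are independent across characteristics and reproducible for a fixed
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `a1c_cohort`: list with `patients` (data frame,
#'   one row per patient) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' table(coh$patients$group)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "a1c_cohort_config"))
  set.seed(config$seed)
  patients <- rbind(generate_group(config, "poc"),
                    generate_group(config, "lab"))
  rownames(patients) <- NULL
  structure(list(patients = patients, config = config), class = "a1c_cohort")
}

#' Estimate the per-cycle glycemic-control probability from a cohort
#'
#' Maximum-likelihood estimate under a constant-hazard discrete-time model:
#' each assessable patient contributes one Bernoulli trial per cycle at risk
#' (up to and including the control cycle, or the full follow-up when
#' censored), so `p_hat = events / trials`. The confidence interval is the
#' Clopper-Pearson binomial interval on the same counts.
#'
#' @param cohort An `a1c_cohort` from [generate_cohort()] (or read with
#'   [read_cohort_csv()]).
#' @param group `"poc"` or `"lab"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `a1c_control_rate`: list with `group`, `p_hat`,
#'   `ci_low`, `ci_high`, `n_used` (assessable patients), `events`, `trials`.
#' @export
estimate_control_rate <- function(cohort, group = c("poc", "lab"),
                                  conf_level = 0.95) {
  stopifnot(inherits(cohort, "a1c_cohort"))
  group <- match.arg(group)
  pts <- cohort$patients[cohort$patients$group == group, , drop = FALSE]
  assessable <- pts[!is.na(pts$baseline_a1c), , drop = FALSE]
  if (nrow(assessable) == 0)
    stop(sprintf("no assessable patients in group '%s'", group), call. = FALSE)
  K <- cohort$config$followup_cycles
  ctrl <- assessable$controlled_at_cycle
  events <- sum(!is.na(ctrl))
  trials <- sum(ifelse(is.na(ctrl), K, ctrl))
  p_hat <- events / trials
  ci <- stats::binom.test(events, trials, conf.level = conf_level)$conf.int
  structure(list(group = group, p_hat = p_hat,
                 ci_low = ci[1], ci_high = ci[2],
                 n_used = nrow(assessable), events = events, trials = trials),
            class = "a1c_control_rate")
}

#' @export
print.a1c_control_rate <- function(x, ...) {
  cat(sprintf(
    "Per-cycle control rate, group '%s': %.4f (95%% CI %.4f-%.4f; %d events / %d patient-cycles, n = %d)\n",
    x$group, x$p_hat, x$ci_low, x$ci_high, x$events, x$trials, x$n_used))
  invisible(x)
}

#' Baseline characteristics of a cohort
#'
#' Per-group summary mirroring a baseline table: group size, availability of
#' A1c results, sex split, age, baseline A1c median and interquartile range
#' (among patients with results), hypertension prevalence, and the fraction
#' ever reaching the target during follow-up.
#'
#' @param cohort An `a1c_cohort`.
#' @return Data frame with one row per group, suitable for CSV export.
#' @export
summarize_baseline <- function(cohort) {
  stopifnot(inherits(cohort, "a1c_cohort"))
  pts <- cohort$patients
  if (nrow(pts) == 0) stop("empty cohort", call. = FALSE)
  do.call(rbind, lapply(unique(pts$group), function(grp) {
    p <- pts[pts$group == grp, , drop = FALSE]
    a1c <- p$baseline_a1c[!is.na(p$baseline_a1c)]
    q <- if (length(a1c)) stats::quantile(a1c, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(
      group = grp,
      n = nrow(p),
      n_a1c_available = sum(!is.na(p$baseline_a1c)),
      frac_a1c_available = mean(!is.na(p$baseline_a1c)),
      frac_male = mean(p$sex == "male"),
      age_mean = mean(p$age),
      age_sd = stats::sd(p$age),
      a1c_median = q[2],
      a1c_q25 = q[1],
      a1c_q75 = q[3],
      frac_hypertension = mean(p$hypertension),
      frac_ever_controlled = mean(!is.na(p$controlled_at_cycle)),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write / read a cohort as CSV
#'
#' The CSV carries one row per patient with header
#' `id,group,sex,age,hypertension,baseline_a1c,controlled_at_cycle`; empty
#' fields encode missing values.
#'
#' @param cohort An `a1c_cohort`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns an `a1c_cohort` (with the supplied or a default configuration
#'   attached).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "a1c_cohort"))
  utils::write.csv(cohort$patients, path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param config Optional [cohort_config()] to attach on read.
#' @export
read_cohort_csv <- function(path, config = cohort_config()) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character", group = "character",
                                        sex = "character"))
  expected <- c("id", "group", "sex", "age", "hypertension", "baseline_a1c",
                "controlled_at_cycle")
  if (!identical(names(pts), expected))
    stop("cohort CSV must have header ", paste(expected, collapse = ","),
         call. = FALSE)
  pts$hypertension <- as.logical(pts$hypertension)
  pts$controlled_at_cycle <- as.integer(pts$controlled_at_cycle)
  structure(list(patients = pts, config = config), class = "a1c_cohort")
}

#' @export
print.a1c_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%s)\n", nrow(x$patients),
              paste(sprintf("%s n=%d", names(table(x$patients$group)),
                            as.integer(table(x$patients$group))),
                    collapse = ", ")))
  invisible(x)
}
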