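#' Read a parameter from a model configuration by path
#'
#' Paths address scalar parameters with dot notation, e.g.
#' `"general_annual_cost"`, `"complication_costs_annual.nephropathy"`,
#' `"occurrence_probs_annual.hospitalization"` or
#' `"strategies.poc.control_prob_per_cycle"`.
#'
#' @param config A [model_config()].
#' @param path Parameter path string.
#' @return The scalar value.
#' @export
config_get_param <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts) {
    if (is.list(node)) {
      if (is.null(node[[p]]))
        stop(sprintf("unknown parameter path '%s' (no element '%s')", path, p),
             call. = FALSE)
      node <- node[[p]]
    } else if (is.numeric(node) && !is.null(names(node)) && p %in% names(node)) {
      node <- node[[p]]
    } else {
      stop(sprintf("unknown parameter path '%s' (no element '%s')", path, p),
           call. = FALSE)
    }
  }
  if (!is.numeric(node) || length(node) != 1)
    stop(sprintf("path '%s' does not address a scalar parameter", path),
         call. = FALSE)
  unname(node)
}

#' Set a parameter in a model configuration by path
#'
#' @inheritParams config_get_param
#' @param value New scalar value.
#' @return The modified configuration.
#' @export
config_set_param <- function(config, path, value) {
  config_get_param(config, path)  # validates the path
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(node, parts) {
    p <- parts[[1]]
    if (length(parts) == 1) {
      node[[p]] <- value
    } else {
      node[[p]] <- set_rec(node[[p]], parts[-1])
    }
    node
  }
  out <- set_rec(unclass(config), parts)
  class(out) <- class(config)
  out
}

#' Declare a sampling distribution for one parameter
#'
#' Distributions are parameterized by method of moments from a mean (the base
#' value by default) and a standard deviation equal to `dispersion * mean`.
#' `beta` is for probabilities, `gamma` for non-negative costs, `uniform`
#' uses `bounds` when given (otherwise mean +/- sqrt(3) sd) and `fixed` pins
#' the parameter at its mean. A mean of zero collapses any family to `fixed`.
#'
#' @param parameter_path Path into the configuration (see
#'   [config_get_param()]).
#' @param family One of `"beta"`, `"gamma"`, `"uniform"`, `"fixed"`.
#' @param mean Distribution mean; `NULL` uses the configured base value.
#' @param dispersion Standard deviation as a fraction of the mean
#'   (default 0.2).
#' @param bounds Optional `c(low, high)` for `uniform`.
#' @return An object of class `a1c_param_distribution`.
#' @export
param_distribution <- function(parameter_path,
                               family = c("beta", "gamma", "uniform", "fixed"),
                               mean = NULL, dispersion = 0.2, bounds = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(parameter_path), length(parameter_path) == 1)
  check_nonneg(dispersion, "dispersion")
  if (!is.null(bounds)) stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
  structure(list(parameter_path = parameter_path, family = family,
                 mean = mean, dispersion = dispersion, bounds = bounds),
            class = "a1c_param_distribution")
}

# Draw one value from a declared distribution; errors name the parameter when
# the method-of-moments parameterization is infeasible.
sample_param <- function(dist, base_value) {
  m <- if (is.null(dist$mean)) base_value else dist$mean
  s <- dist$dispersion * m
  if (dist$family == "fixed" || s == 0 || m == 0) return(m)
  switch(dist$family,
    beta = {
      if (m >= 1)
        return(m)
      if (s^2 >= m * (1 - m))
        stop(sprintf(
          "parameter '%s': beta method-of-moments infeasible (mean %.4g, sd %.4g)",
          dist$parameter_path, m, s), call. = FALSE)
      nu <- m * (1 - m) / s^2 - 1
      stats::rbeta(1, m * nu, (1 - m) * nu)
    },
    gamma = {
      shape <- (m / s)^2
      stats::rgamma(1, shape = shape, rate = shape / m)
    },
    uniform = {
      if (!is.null(dist$bounds)) {
        stats::runif(1, dist$bounds[1], dist$bounds[2])
      } else {
        stats::runif(1, m - sqrt(3) * s, m + sqrt(3) * s)
      }
    }
  )
}

#' Default probabilistic-sensitivity distributions
#'
#' Beta distributions for every probability parameter (complication occurrence
#' and case fatality, per-cycle control probabilities) and gamma distributions
#' for every cost parameter (complication and general annual costs, test and
#' device costs), each centred on its base value with a standard deviation of
#' `dispersion` times the base value.
#'
#' @param config A [model_config()].
#' @param dispersion Standard deviation as a fraction of the mean
#'   (default 0.2).
#' @return List of [param_distribution()] objects.
#' @export
default_psa_distributions <- function(config, dispersion = 0.2) {
  stopifnot(inherits(config, "a1c_model_config"))
  dists <- list(param_distribution("general_annual_cost", "gamma",
                                   dispersion = dispersion))
  for (s in complication_states()) {
    dists <- c(dists, list(
      param_distribution(paste0("complication_costs_annual.", s), "gamma",
                         dispersion = dispersion),
      param_distribution(paste0("occurrence_probs_annual.", s), "beta",
                         dispersion = dispersion),
      param_distribution(paste0("death_probs_annual.", s), "beta",
                         dispersion = dispersion)))
  }
  for (nm in names(config$strategies)) {
    strat <- config$strategies[[nm]]
    dists <- c(dists, list(
      param_distribution(paste0("strategies.", nm, ".control_prob_per_cycle"),
                         "beta", dispersion = dispersion),
      param_distribution(paste0("strategies.", nm, ".test_cost_per_test"),
                         "gamma", dispersion = dispersion)))
    if (strat$device_cost > 0)
      dists <- c(dists, list(
        param_distribution(paste0("strategies.", nm, ".device_cost"),
                           "gamma", dispersion = dispersion)))
  }
  dists
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Each trial draws every declared parameter independently, rebuilds the model
#' and evaluates all strategies. Results are reproducible bit-for-bit for a
#' fixed seed.
#'
#' @param config A [model_config()] with at least two strategies.
#' @param distributions List of [param_distribution()] objects; default
#'   [default_psa_distributions()].
#' @param n_trials Number of Monte Carlo trials (default 1000).
#' @param seed Integer seed for the random draws.
#' @param wtp_grid WTP grid for the acceptance curve (default 0 to 5000 by
#'   100).
#' @param intervention,comparator Strategy names for the incremental
#'   quantities; default the first and second configured strategy.
#' @return An object of class `a1c_psa_result`: list with `n_trials`, `seed`,
#'   `per_trial` (data frame of cost and effectiveness per strategy plus
#'   incremental pair), `percentile_summary` (2.5th/97.5th percentile per
#'   quantity), `ce_plane` (`delta_effect`, `delta_cost` per trial) and
#'   `nmb_acceptance` (fraction of trials with positive incremental NMB per
#'   WTP).
#' @export
run_psa <- function(config, distributions = default_psa_distributions(config),
                    n_trials = 1000, seed = 1L,
                    wtp_grid = seq(0, 5000, by = 100),
                    intervention = names(config$strategies)[1],
                    comparator = names(config$strategies)[2]) {
  stopifnot(inherits(config, "a1c_model_config"), n_trials >= 1)
  if (length(config$strategies) < 2)
    stop("PSA requires at least two strategies", call. = FALSE)
  base_values <- vapply(distributions, function(d)
    config_get_param(config, d$parameter_path), numeric(1))
  set.seed(as.integer(seed))
  strat_names <- names(config$strategies)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg_i <- config
    for (j in seq_along(distributions)) {
      v <- sample_param(distributions[[j]], base_values[[j]])
      cfg_i <- config_set_param(cfg_i, distributions[[j]]$parameter_path, v)
    }
    out <- evaluate_strategies(cfg_i)
    costs <- vapply(out, `[[`, numeric(1), "discounted_cost")
    effs <- vapply(out, `[[`, numeric(1), "effectiveness")
    rows[[i]] <- c(costs, effs)
  }
  per_trial <- as.data.frame(do.call(rbind, rows))
  names(per_trial) <- c(paste0("cost_", strat_names),
                        paste0("eff_", strat_names))
  per_trial$delta_cost <- per_trial[[paste0("cost_", intervention)]] -
    per_trial[[paste0("cost_", comparator)]]
  per_trial$delta_effect <- per_trial[[paste0("eff_", intervention)]] -
    per_trial[[paste0("eff_", comparator)]]
  per_trial <- cbind(trial = seq_len(n_trials), per_trial)

  qs <- t(vapply(setdiff(names(per_trial), "trial"), function(nm)
    stats::quantile(per_trial[[nm]], c(0.025, 0.975), names = FALSE),
    numeric(2)))
  percentile_summary <- data.frame(quantity = rownames(qs),
                                   p2.5 = qs[, 1], p97.5 = qs[, 2],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE)
  nmb_acceptance <- data.frame(
    wtp = wtp_grid,
    prob_intervention = vapply(wtp_grid, function(w)
      mean(w * per_trial$delta_effect - per_trial$delta_cost > 0), numeric(1)))
  structure(list(
    n_trials = n_trials, seed = as.integer(seed),
    intervention = intervention, comparator = comparator,
    per_trial = per_trial,
    percentile_summary = percentile_summary,
    ce_plane = per_trial[, c("delta_effect", "delta_cost")],
    nmb_acceptance = nmb_acceptance
  ), class = "a1c_psa_result")
}

#' @export
print.a1c_psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo trials (seed %d), '%s' vs '%s'\n",
              x$n_trials, x$seed, x$intervention, x$comparator))
  print(x$percentile_summary, digits = 5)
  invisible(x)
}

#' Default one-way sensitivity ranges
#'
#' The literature-derived parameter ledger (complication and general annual
#' costs, occurrence and case-fatality probabilities) varied by +/- 20% of
#' the base value. The strategy parameters (control rates, test and device
#' costs) are study or invoice quantities and are not part of the default
#' sweep; supply explicit ranges to include them.
#'
#' @param config A [model_config()].
#' @param fraction Half-width as a fraction of the base value (default 0.2).
#' @return Data frame with columns `parameter_path`, `low`, `high`.
#' @export
default_tornado_ranges <- function(config, fraction = 0.2) {
  stopifnot(inherits(config, "a1c_model_config"))
  paths <- c("general_annual_cost",
             paste0("complication_costs_annual.", complication_states()),
             paste0("occurrence_probs_annual.", complication_states()),
             paste0("death_probs_annual.", complication_states()))
  base <- vapply(paths, function(p) config_get_param(config, p), numeric(1))
  data.frame(parameter_path = paths,
             low = (1 - fraction) * base,
             high = (1 + fraction) * base,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each parameter in turn to its low and high value, all others at base
#' case, and records the incremental net monetary benefit of the intervention
#' at the given willingness-to-pay. Entries are ranked by descending impact
#' width.
#'
#' @param config A [model_config()] with at least two strategies.
#' @param parameter_ranges Data frame with columns `parameter_path`, `low`,
#'   `high` (default [default_tornado_ranges()]).
#' @param wtp Willingness-to-pay threshold in US$ per unit effectiveness
#'   (default 2000).
#' @param intervention,comparator Strategy names; default first and second.
#' @return Data frame of class `a1c_tornado` with columns `parameter_path`,
#'   `low_input`, `high_input`, `outcome_low`, `outcome_high`, `width`,
#'   sorted by descending `width`.
#' @export
tornado <- function(config, parameter_ranges = default_tornado_ranges(config),
                    wtp = 2000,
                    intervention = names(config$strategies)[1],
                    comparator = names(config$strategies)[2]) {
  stopifnot(inherits(config, "a1c_model_config"), wtp >= 0)
  stopifnot(all(c("parameter_path", "low", "high") %in% names(parameter_ranges)))
  if (any(parameter_ranges$low > parameter_ranges$high))
    stop("each range must have low <= high", call. = FALSE)
  inmb <- function(cfg) {
    out <- evaluate_strategies(cfg)
    de <- out[[intervention]]$effectiveness - out[[comparator]]$effectiveness
    dc <- out[[intervention]]$discounted_cost -
      out[[comparator]]$discounted_cost
    wtp * de - dc
  }
  res <- do.call(rbind, lapply(seq_len(nrow(parameter_ranges)), function(i) {
    path <- parameter_ranges$parameter_path[i]
    lo <- inmb(config_set_param(config, path, parameter_ranges$low[i]))
    hi <- inmb(config_set_param(config, path, parameter_ranges$high[i]))
    data.frame(parameter_path = path,
               low_input = parameter_ranges$low[i],
               high_input = parameter_ranges$high[i],
               outcome_low = lo, outcome_high = hi,
               width = abs(hi - lo),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$width, res$parameter_path), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("a1c_tornado", class(res))
  res
}
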