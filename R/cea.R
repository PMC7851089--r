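#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes the incremental cost and effectiveness of an intervention against
#' a comparator, classifies dominance, and reports the incremental
#' cost-effectiveness ratio (ICER) from full-precision deltas. The ICER is
#' absent (`NA`) when one strategy dominates or when the effectiveness delta
#' is zero (undefined ratio).
#'
#' Dominance is classified on the sign quadrant of the deltas:
#' `intervention_dominates` when the intervention costs no more and is at
#' least as effective (excluding exact ties on both), `comparator_dominates`
#' in the mirrored case, otherwise `none`. Exact ties on both deltas classify
#' as `none`.
#'
#' @param intervention,comparator `a1c_strategy_outcome` objects from
#'   [accrue_outcomes()] or [evaluate_strategies()].
#' @return An object of class `a1c_cea_comparison`: list with `intervention`,
#'   `comparator`, `delta_cost`, `delta_effect`, `icer`, `dominance`.
#' @examples
#' o <- evaluate_strategies(reference_config())
#' cea_compare(o$poc, o$lab)
#' @export
cea_compare <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "a1c_strategy_outcome"),
            inherits(comparator, "a1c_strategy_outcome"))
  dc <- intervention$discounted_cost - comparator$discounted_cost
  de <- intervention$effectiveness - comparator$effectiveness
  dominance <- if (dc == 0 && de == 0) {
    "none"
  } else if (dc <= 0 && de >= 0) {
    "intervention_dominates"
  } else if (dc >= 0 && de <= 0) {
    "comparator_dominates"
  } else {
    "none"
  }
  icer <- if (dominance == "none" && de != 0) dc / de else NA_real_
  structure(list(
    intervention = intervention,
    comparator = comparator,
    delta_cost = dc,
    delta_effect = de,
    icer = icer,
    dominance = dominance
  ), class = "a1c_cea_comparison")
}

#' @export
print.a1c_cea_comparison <- function(x, ...) {
  cat(sprintf("CEA: '%s' vs '%s'\n", x$intervention$strategy,
              x$comparator$strategy))
  cat(sprintf("  incremental cost:          %10.2f US$/patient\n", x$delta_cost))
  cat(sprintf("  incremental effectiveness: %10.4f\n", x$delta_effect))
  if (is.na(x$icer)) {
    cat(sprintf("  ICER: undefined (dominance: %s)\n", x$dominance))
  } else {
    cat(sprintf("  ICER: %.2f US$ per unit effectiveness (dominance: %s)\n",
                x$icer, x$dominance))
  }
  invisible(x)
}

#' Net monetary benefit across a willingness-to-pay grid
#'
#' For each strategy and willingness-to-pay (WTP) value,
#' `NMB = WTP * effectiveness - cost`; the incremental NMB of the intervention
#' over the comparator is `WTP * delta_effect - delta_cost` and crosses zero
#' at the ICER when no strategy dominates.
#'
#' @param outcomes Named list of `a1c_strategy_outcome` objects.
#' @param wtp_grid Non-negative WTP values (US$ per unit effectiveness).
#'   Default 0 to 5000 in steps of 100.
#' @param intervention,comparator Strategy names for the incremental column;
#'   default the first and second outcome.
#' @return Data frame in long format with columns `wtp`, `strategy`, `nmb`,
#'   `incremental_nmb` (incremental value repeated within each WTP).
#' @export
nmb_curve <- function(outcomes, wtp_grid = seq(0, 5000, by = 100),
                      intervention = names(outcomes)[1],
                      comparator = names(outcomes)[2]) {
  stopifnot(length(outcomes) >= 1, length(wtp_grid) >= 1, all(wtp_grid >= 0))
  res <- do.call(rbind, lapply(names(outcomes), function(nm) {
    o <- outcomes[[nm]]
    data.frame(wtp = wtp_grid, strategy = nm,
               nmb = wtp_grid * o$effectiveness - o$discounted_cost,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(intervention) && !is.null(comparator) &&
      !is.na(intervention) && !is.na(comparator)) {
    de <- outcomes[[intervention]]$effectiveness -
      outcomes[[comparator]]$effectiveness
    dc <- outcomes[[intervention]]$discounted_cost -
      outcomes[[comparator]]$discounted_cost
    inc <- data.frame(wtp = wtp_grid, incremental_nmb = wtp_grid * de - dc)
    res <- merge(res, inc, by = "wtp", sort = TRUE)
  }
  res[order(res$wtp, res$strategy), , drop = FALSE]
}
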