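# Optional ggplot2 figures; the analysis never depends on them.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers", call. = FALSE)
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' Scatter of incremental effectiveness vs incremental cost across Monte Carlo
#' trials, with the willingness-to-pay threshold line.
#'
#' @param psa An `a1c_psa_result`.
#' @param wtp Threshold slope to draw (default 2000).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 2000) {
  need_ggplot()
  ggplot2::ggplot(psa$ce_plane,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental effectiveness",
                  y = "Incremental cost (US$)",
                  title = sprintf("CE plane (%d trials)", psa$n_trials)) +
    ggplot2::theme_minimal()
}

#' Plot net-monetary-benefit curves
#'
#' @param curve Data frame from [nmb_curve()].
#' @return A ggplot object.
#' @export
plot_nmb <- function(curve) {
  need_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$nmb,
                                      colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (US$ per unit effectiveness)",
                  y = "Net monetary benefit (US$)") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the low- to the high-input outcome per parameter,
#' ranked by width.
#'
#' @param tor An `a1c_tornado` from [tornado()].
#' @param top Number of parameters to show (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, top = nrow(tor)) {
  need_ggplot()
  df <- utils::head(as.data.frame(unclass(tor)), top)
  df$parameter_path <- factor(df$parameter_path,
                              levels = rev(df$parameter_path))
  base <- (df$outcome_low + df$outcome_high) / 2
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter_path)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_low,
                                       xend = .data$outcome_high,
                                       yend = .data$parameter_path),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "Incremental net monetary benefit (US$)", y = NULL) +
    ggplot2::theme_minimal()
}
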