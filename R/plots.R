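#' Plot a belief trajectory
#'
#' Predictive fairness and posterior HI/SI marginals over trials, faceted by
#' dictator block, with the observed splits shown as rug marks.
#'
#' @param trajectory Output of [belief_trajectory()].
#' @return A ggplot object.
#' @export
plot_belief_trajectory <- function(trajectory) {
  long <- trajectory |>
    tidyr::pivot_longer(c("predict_fair", "hi_marginal", "si_marginal"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial_index, y = .data$value,
                                     color = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = dplyr::filter(trajectory, .data$outcome == "fair"),
      ggplot2::aes(x = .data$trial_index), inherit.aes = FALSE,
      sides = "t", length = ggplot2::unit(0.05, "npc")
    ) +
    ggplot2::facet_wrap(~block_position, nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "trial", y = "probability", color = NULL,
                  title = "Belief trajectory",
                  subtitle = "rug marks = fair splits observed") +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Per-participant BIC scatter for two models with the equality line and the
#' conventional |dBIC| = threshold evidence bands.
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cr_comparison <- function(x, ...) {
  ggplot2::ggplot(x$table, ggplot2::aes(x = .data$bic_a, y = .data$bic_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "red") +
    ggplot2::geom_abline(slope = 1, intercept = c(-x$threshold, x$threshold),
                         color = "grey60", linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("BIC,", x$names[1]), y = paste("BIC,", x$names[2]),
                  title = sprintf("Model comparison: %s vs %s", x$names[1],
                                  x$names[2]),
                  subtitle = sprintf(
                    "median BIC %.1f vs %.1f; %d vs %d participants beyond dBIC = %g",
                    x$median_bic[1], x$median_bic[2], x$n_favoring_a,
                    x$n_favoring_b, x$threshold)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot parameter recovery
#'
#' Generating vs. recovered transformed parameter values, one facet per free
#' parameter, with the identity line and the recovery correlation in the
#' facet label.
#'
#' @param recovery Output of [parameter_recovery()].
#' @param parameters Optional subset of parameter names.
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery, parameters = NULL) {
  sm <- recovery$summary
  if (!is.null(parameters)) sm <- dplyr::filter(sm, .data$parameter %in% parameters)
  long <- purrr::map_dfr(sm$parameter, function(nm) {
    tibble(parameter = sprintf("%s (r = %.2f)", nm,
                               sm$correlation[sm$parameter == nm]),
           generating = recovery$params[[paste0(nm, "_gen")]],
           recovered = recovery$params[[paste0(nm, "_fit")]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generating, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating (transformed)", y = "recovered (transformed)",
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}
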