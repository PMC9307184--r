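#' Plot an inclusion summary (cut-point diagnostic scatter)
#'
#' Inclusion probability against the slab-coefficient mean, the plot used
#' to eyeball a cut point: non-contributors cluster near a zero
#' coefficient at low `p_hat`, contributors separate along both axes.
#'
#' @param object an `inclusion_summary` from [summarize_trace()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.inclusion_summary <- function(object, ...) {
  cutoff <- attr(object, "cutoff") %||% 0.3
  ggplot2::ggplot(scatter_summary(object),
                  ggplot2::aes(x = .data$beta_hat_included, y = .data$p_hat,
                               shape = .data$contributor)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 1, `FALSE` = 16),
                                name = "contributor") +
    ggplot2::labs(x = expression(hat(beta)[included]),
                  y = expression(hat(p))) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a `roc_result` from [roc_from_scores()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("%s, AUC = %.3f",
                                     attr(object, "method") %||% "",
                                     attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a performance sweep
#'
#' Mean +/- SD of each confusion metric across the sweep grid, one panel
#' per metric, coloured by method.
#'
#' @param sweep tibble returned by [performance_sweep()].
#' @return a ggplot object.
#' @export
plot_performance_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$value, y = .data$mean,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd), size = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = unique(sweep$vary), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MCMC traces of the scalar parameters
#'
#' @param trace a `bracod_trace`.
#' @return a ggplot object with one panel per scalar parameter.
#' @export
plot_trace_scalars <- function(trace) {
  stopifnot(inherits(trace, "bracod_trace"))
  df <- tibble(draw = seq_along(trace$draws$alpha),
               alpha = trace$draws$alpha,
               sigma2 = trace$draws$sigma2,
               tau2 = trace$draws$tau2)
  long <- tidyr::pivot_longer(df, -"draw", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}
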