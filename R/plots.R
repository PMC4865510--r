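#' Plot the per-minute DCL time course
#'
#' One point per minute and condition; the alert session should sit high and
#' drift down, the sleep-deprived one hover low.
#'
#' @param object A `dcl_record`, or the `dcl` tibble of a `fatigue_report`
#'   (columns `minute`, `dcl`, optionally `condition`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcl_record <- function(object, ...) {
  df <- as_tibble(object)
  if (!"condition" %in% names(df)) {
    df$condition <- attr(object, "condition") %||% "session"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minute, y = .data$dcl,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 3)) +
    ggplot2::labs(x = "Minute of driving", y = "DCL",
                  colour = NULL, title = "Driving condition level over time") +
    ggplot2::theme_minimal()
}

#' Scatter the alpha/beta region RPL features by condition
#'
#' The classic separation plot: well-rested trials cluster toward low-alpha
#' high-beta, sleep-deprived trials toward high-alpha low-beta.
#'
#' @param features Tibble with columns `alpha_cp`, `beta_fc`, `condition`.
#' @return A ggplot object.
#' @export
plot_rpl_scatter <- function(features) {
  stopifnot(all(c("alpha_cp", "beta_fc", "condition") %in% names(features)))
  ggplot2::ggplot(features, ggplot2::aes(x = .data$alpha_cp, y = .data$beta_fc,
                                         colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Centro-parietal alpha RPL",
                  y = "Fronto-central beta RPL", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the modality contributions to the DCL difference
#'
#' @param contributions Tibble from [modality_contributions()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(contributions) {
  ggplot2::ggplot(contributions,
                  ggplot2::aes(x = .data$modality, y = .data$contribution,
                               fill = .data$modality)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Contribution to DCL difference") +
    ggplot2::theme_minimal()
}

#' Plot per-modality and fused classification accuracies
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = stats::reorder(.data$modality,
                                                  .data$mean_accuracy),
                               y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Mean accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
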