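#' Volcano plot of a screen result
#'
#' Loss-response coefficient against -log10 p, coloured by hit class.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$testable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient,
                                   y = -log10(.data$p),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      compensation = "#D55E00", collateral_loss = "#0072B2",
      none = "grey70")) +
    ggplot2::labs(x = "loss coefficient (log2 units)",
                  y = expression(-log[10](p)),
                  colour = NULL,
                  title = sprintf("Loss-response screen (%s layer)",
                                  attr(object, "layer") %||% "?")) +
    ggplot2::theme_minimal()
}

#' Forest plot of enrichment odds ratios
#'
#' @param report Output of [binary_battery()] (or any tibble with
#'   `feature`, `odds_ratio`, `fdr`, `comparison`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(report) {
  df <- report |>
    dplyr::filter(is.finite(.data$odds_ratio), .data$odds_ratio > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = .data$feature,
                                   colour = .data$fdr < 0.05)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "odds ratio", y = NULL, colour = "FDR < 5%") +
    ggplot2::theme_minimal()
}

#' Forest plot of model odds ratios
#'
#' @param object A `model_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_report
#' @export
autoplot.model_report <- function(object, ...) {
  df <- object$coefficients |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of mechanism calls
#'
#' @param mechanism_calls Output of [classify_mechanism()].
#' @return A ggplot object.
#' @export
plot_mechanism <- function(mechanism_calls) {
  df <- mechanism_calls |>
    dplyr::filter(.data$class != "none") |>
    dplyr::count(.data$class, .data$mechanism)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mechanism, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "directed hit pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
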