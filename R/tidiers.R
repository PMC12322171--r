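#' Tidy an OLS fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return A tibble with one row per retained design column: `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$t_statistics),
                 p.value = unname(x$p_values))
}

#' One-row summary of an OLS fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return A tibble: `nobs`, `df.residual`, `sigma`, `n_dropped_columns`.
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_obs, df.residual = x$residual_df,
                 sigma = sqrt(sum(x$residuals^2) / x$residual_df),
                 n_dropped_columns = length(x$dropped))
}

#' Tidy a logistic model report
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return The coefficient tibble: `term`, `estimate`, `std.error`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p.value`.
#' @method tidy model_report
#' @export
tidy.model_report <- function(x, ...) x$coefficients

#' One-row summary of a logistic model report
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return A tibble: `auc_selected`, `auc_full`, `n_complete_cases`,
#'   `n_features`, `separation_flag`.
#' @method glance model_report
#' @export
glance.model_report <- function(x, ...) {
  tibble::tibble(auc_selected = x$auc_selected, auc_full = x$auc_full,
                 n_complete_cases = x$n_complete_cases,
                 n_features = length(x$selected_features),
                 separation_flag = x$separation_flag)
}

#' Summarize a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A tibble: `layer`, `n_tested`, `n_compensation`,
#'   `n_collateral_loss`, `n_untestable`.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    layer = attr(x, "layer") %||% unique(x$layer),
    n_tested = sum(x$testable),
    n_compensation = sum(x$class == "compensation", na.rm = TRUE),
    n_collateral_loss = sum(x$class == "collateral_loss", na.rm = TRUE),
    n_untestable = sum(!x$testable))
}
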