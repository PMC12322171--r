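#' Rank features by AUC, inverting negative predictors
#'
#' Scores every feature column by rank-based AUC against a binary label on
#' that feature's complete cases. Features scoring below 0.5 are negative
#' predictors: they are flagged and re-scored after sign inversion so that
#' every reported AUC is at least 0.5.
#'
#' @param features Data frame of numeric feature columns (flags coerced
#'   to 0/1).
#' @param labels Binary vector (both classes present).
#' @return A tibble sorted by decreasing `auc`: `feature`, `auc`,
#'   `inverted`.
#' @export
feature_auc_ranking <- function(features, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels[!is.na(labels)])) < 2) {
    rlang::abort("labels must contain both classes")
  }
  purrr::map(names(features), function(f) {
    v <- as.numeric(features[[f]])
    auc <- rank_auc(v, labels)
    inv <- auc < 0.5
    tibble::tibble(feature = f, auc = ifelse(inv, 1 - auc, auc),
                   inverted = inv)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$auc))
}

#' Prepare the modeling design matrix
#'
#' Turns the assembled pair-feature table into a numeric design for
#' logistic modeling of one task. For the compensation task, pairs classed
#' as collateral loss are removed (and vice versa) so the contrast is
#' hits vs never-hits. High-missingness features are dropped; the two
#' paralog lengths are aggregated into one mean-length column; listwise
#' deletion yields the complete-case analysis set; continuous features are
#' z-scored on that set; finally AUC-negative features are sign-inverted
#' so all coefficients share an interpretation.
#'
#' @param features Feature tibble from [assemble_features()].
#' @param task `"compensation"` or `"collateral_loss"`.
#' @param high_missing_cutoff Features missing in more than this fraction
#'   of rows are dropped (default 0.4).
#' @param min_cases Minimum complete cases (default 50).
#' @return A list: `design` (numeric matrix, no intercept), `labels`
#'   (0/1), `auc_ranking`, `dropped_features`, `n_complete_cases`.
#' @export
prepare_design <- function(features,
                           task = c("compensation", "collateral_loss"),
                           high_missing_cutoff = 0.4, min_cases = 50) {
  task <- match.arg(task)
  other <- setdiff(c("compensation", "collateral_loss"), task)
  df <- features |> dplyr::filter(.data$pair_class != other)
  labels <- as.integer(df$pair_class == task)
  drop_id <- c("gene_a", "gene_b", "lost_gene", "responder_gene",
               "pair_class")
  feats <- df |> dplyr::select(-dplyr::any_of(drop_id))
  if (all(c("length_lost", "length_responder") %in% names(feats))) {
    feats <- feats |>
      dplyr::mutate(mean_paralog_length =
                      (.data$length_lost + .data$length_responder) / 2) |>
      dplyr::select(-"length_lost", -"length_responder")
  }
  miss <- purrr::map_dbl(feats, ~ mean(is.na(.x)))
  dropped <- names(feats)[miss > high_missing_cutoff]
  feats <- feats[, miss <= high_missing_cutoff, drop = FALSE]
  feats <- dplyr::mutate(feats, dplyr::across(dplyr::everything(),
                                              as.numeric))
  cc <- stats::complete.cases(feats)
  feats <- feats[cc, , drop = FALSE]
  labels <- labels[cc]
  if (nrow(feats) < min_cases) {
    rlang::abort(sprintf("only %d complete cases (< %d)", nrow(feats),
                         min_cases))
  }
  is_binary <- purrr::map_lgl(feats, ~ all(.x %in% c(0, 1)))
  feats <- dplyr::mutate(
    feats,
    dplyr::across(dplyr::all_of(names(feats)[!is_binary]),
                  ~ if (stats::sd(.x) > 0) (.x - mean(.x)) / stats::sd(.x)
                    else .x * 0))
  ranking <- feature_auc_ranking(feats, labels)
  for (f in ranking$feature[ranking$inverted]) {
    feats[[f]] <- if (is_binary[[f]]) 1 - feats[[f]] else -feats[[f]]
  }
  list(design = as.matrix(feats), labels = labels, auc_ranking = ranking,
       dropped_features = dropped, n_complete_cases = nrow(feats))
}

#' L1-penalized logistic feature selection
#'
#' Fits a lasso logistic regression under the convention that the
#' objective is `||beta||_1 + C * (summed log-loss)` — `C` weights the
#' data fit, so smaller `C` means stronger shrinkage. The intercept is
#' unpenalized and features are used as given (z-score upstream). Features
#' with non-zero coefficients are selected.
#'
#' @param design Numeric design matrix (no intercept column).
#' @param labels Binary 0/1 labels.
#' @param penalty_c Data-fit weight `C` (default 0.01).
#' @return Character vector of selected feature names (possibly empty).
#' @export
lasso_select <- function(design, labels, penalty_c = 0.01) {
  n <- nrow(design)
  lambda_target <- 1 / (penalty_c * n)
  lambda_max <- max(abs(crossprod(design, labels - mean(labels)))) / n
  lambdas <- sort(unique(c(
    exp(seq(log(max(lambda_max, lambda_target * 1.001)),
            log(lambda_target), length.out = 30)))), decreasing = TRUE)
  fit <- glmnet::glmnet(design, labels, family = "binomial", alpha = 1,
                        lambda = lambdas, standardize = FALSE,
                        maxit = 1e6)
  if (!all(fit$lambda == lambdas) || fit$jerr != 0) {
    rlang::abort("lasso path did not converge; inspect the design scaling")
  }
  j <- which.min(abs(fit$lambda - lambda_target))
  beta <- as.numeric(fit$beta[, j])
  colnames(design)[abs(beta) > 1e-8]
}

fit_logistic_report <- function(design, labels, selected,
                                auc_full = NA_real_) {
  X <- design[, selected, drop = FALSE]
  dat <- data.frame(y = labels, X, check.names = FALSE)
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  # strip glm backtick-quoting of non-syntactic names
  terms <- gsub("`", "", terms)
  coefs <- tibble::tibble(
    term = terms,
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    odds_ratio = exp(unname(sm[, 1])),
    ci_low = exp(unname(sm[, 1] - 1.96 * sm[, 2])),
    ci_high = exp(unname(sm[, 1] + 1.96 * sm[, 2])),
    p.value = unname(sm[, 4])
  )
  structure(
    list(selected_features = selected, coefficients = coefs,
         auc_selected = rank_auc(stats::predict(fit, type = "link"), labels),
         auc_full = auc_full, n_complete_cases = length(labels),
         separation_flag = sep_flag, fit = fit),
    class = "model_report")
}

#' Fit the final logistic model on selected features
#'
#' Unpenalized maximum-likelihood logistic regression on the
#' lasso-selected features, with Wald standard errors, odds ratios and
#' 95% confidence intervals, plus in-sample AUCs for both the
#' selected-feature model and the unregularized all-feature model. Perfect
#' separation is flagged; its confidence intervals are then unreliable.
#'
#' @param design Numeric design matrix.
#' @param labels Binary 0/1 labels.
#' @param selected Selected feature names (at least one).
#' @return A `model_report`: `selected_features`, `coefficients` tibble
#'   (term, estimate, std.error, odds_ratio, ci_low, ci_high, p.value),
#'   `auc_selected`, `auc_full`, `n_complete_cases`, `separation_flag`.
#' @export
fit_final_model <- function(design, labels, selected) {
  if (length(selected) == 0) {
    rlang::abort("no selected features; cannot fit final model")
  }
  full <- fit_logistic_report(design, labels, colnames(design))
  rep <- fit_logistic_report(design, labels, selected,
                             auc_full = full$auc_selected)
  rep
}

#' Synthetic-lethality-augmented compensation model
#'
#' Unpenalized logistic regression predicting compensation from exactly
#' five predictors: the synthetic-lethality pair label, family size,
#' degree centrality of the lost gene, neighbour essentiality of the lost
#' gene, and the pair Jaccard index.
#'
#' @param design Numeric design matrix containing `family_size`,
#'   `degree_centrality_lost`, `neighbour_essentiality_lost`, `jaccard`.
#' @param labels Binary 0/1 labels.
#' @param sl_flag Binary synthetic-lethality flag per row of `design`.
#' @return A `model_report` with the five predictors.
#' @export
sl_augmented_model <- function(design, labels, sl_flag) {
  need <- c("family_size", "degree_centrality_lost",
            "neighbour_essentiality_lost", "jaccard")
  miss <- setdiff(need, colnames(design))
  if (length(miss) > 0) {
    rlang::abort(sprintf("design lacks predictor(s): %s",
                         paste(miss, collapse = ", ")))
  }
  X <- cbind(synthetic_lethal = as.numeric(sl_flag),
             design[, need, drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(labels)
  fit_logistic_report(X[keep, , drop = FALSE], labels[keep],
                      colnames(X))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %d features, n = %d, AUC %.3f (all features %.3f)%s\n",
    length(x$selected_features), x$n_complete_cases, x$auc_selected,
    x$auc_full,
    if (x$separation_flag) " [perfect separation: CIs unreliable]" else ""))
  print(x$coefficients)
  invisible(x)
}
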