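#' Ordinary least squares with t-based inference
#'
#' Minimal OLS fit used by every regression step of the screens. The design
#' is a named numeric matrix whose first column is normally the intercept.
#' Zero-variance and exactly collinear columns are dropped deterministically
#' before fitting: columns are scanned in the order given and a column is
#' kept only if it increases the design rank, so the first-listed member of
#' any collinear group survives. Inference on each retained coefficient uses
#' the t distribution with `residual_df = n - n_retained` degrees of
#' freedom.
#'
#' Rows with any missing value in the response or design are removed
#' (listwise deletion) before fitting.
#'
#' @param response Numeric response vector.
#' @param design Named numeric matrix (or data frame) of predictors,
#'   including the intercept column.
#' @return An object of class `ols_fit`: named `coefficients`, `se`,
#'   `t_statistics`, `p_values`, `residual_df`, `residuals` (on the retained
#'   observations), `dropped` (names of eliminated columns), `n_obs`.
#' @export
#' @examples
#' x <- c(0, 0, 1, 1)
#' fit <- ols_fit(1 + 0.5 * x, cbind(intercept = 1, x = x))
#' fit$coefficients["x"]
ols_fit <- function(response, design) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) {
    rlang::abort("design columns must be named")
  }
  keep_rows <- stats::complete.cases(X) & !is.na(response)
  X <- X[keep_rows, , drop = FALSE]
  y <- as.numeric(response[keep_rows])
  n <- length(y)
  if (n <= ncol(X)) {
    # may still be fittable after drops; checked again below
  }

  # greedy deterministic rank-based column selection (first-listed kept)
  keep <- logical(ncol(X))
  cur_rank <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- X[, c(which(keep), j), drop = FALSE]
    r <- qr(cand)$rank
    if (r > cur_rank) {
      keep[j] <- TRUE
      cur_rank <- r
    }
  }
  dropped <- colnames(X)[!keep]
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)
  if (p == 0) rlang::abort("degenerate fit: no usable design columns")
  if (ncol(X) > 1 && p == 1 && qr(cbind(Xk, 1))$rank == 1) {
    rlang::abort("degenerate fit: no non-intercept predictors retained")
  }
  if (n <= p) rlang::abort("degenerate fit: fewer observations than predictors")

  qrX <- qr(Xk)
  beta <- qr.coef(qrX, y)
  res <- y - as.numeric(Xk %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  names(beta) <- names(se) <- names(tstat) <- names(pval) <- colnames(Xk)
  structure(
    list(coefficients = beta, se = se, t_statistics = tstat,
         p_values = pval, residual_df = df, residuals = res,
         dropped = dropped, n_obs = n),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %d obs, %d df\n", x$n_obs, x$residual_df))
  print(tidy(x))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1) controlling the false discovery
#' rate. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exact test on a 2x2 table
#'
#' Rows are hit / non-hit, columns feature-present / feature-absent. The
#' odds ratio is the sample cross-product ratio `(a*d)/(b*c)` (the
#' unconditional maximum-likelihood estimate), `Inf` when `b*c == 0` with
#' `a*d > 0` and `NaN` when both products are zero. The two-sided p-value
#' sums hypergeometric point probabilities no larger than the observed
#' one, with table margins fixed.
#'
#' @param a,b,c,d Non-negative counts: `a` hits with feature, `b` hits
#'   without, `c` non-hits with feature, `d` non-hits without.
#' @return A list with `odds_ratio`, `p_value` and the counts.
#' @export
#' @examples
#' exact_2x2(10, 5, 2, 8)$odds_ratio  # 8
exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("2x2 counts must be non-negative integers")
  }
  if (sum(counts) == 0) rlang::abort("empty 2x2 table")
  or <- if (a * d == 0 && b * c == 0) NaN
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  list(odds_ratio = or, p_value = p, a = a, b = b, c = c, d = d)
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Two-tailed equal-variance t-test; Cohen's d is the mean difference
#' standardized by the pooled standard deviation.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @return A list with `t`, `df` (`|x|+|y|-2`), `p_value`, `cohen_d`,
#'   `mean_difference`, `n_x`, `n_y`.
#' @export
pooled_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("pooled_t needs at least 2 values per group")
  }
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) rlang::abort("degenerate: zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    cohen_d = (mean(x) - mean(y)) / sqrt(sp2),
    mean_difference = mean(x) - mean(y),
    n_x = length(x), n_y = length(y)
  )
}

#' Rank-sum test with Cliff's delta
#'
#' Two-sided Mann-Whitney U test reported together with Cliff's delta,
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| * |y|)` (ties contribute 0).
#' For small problems (`|x|*|y| <= 400`) without ties the p-value comes
#' from the exact U distribution; otherwise from the normal approximation
#' with tie correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A list with `U`, `p_value`, `cliffs_delta`, `n_x`, `n_y`.
#' @export
ranksum_cliffs <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) rlang::abort("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # #{x>y} + 0.5 * ties
  delta <- (2 * U - m * n) / (m * n)
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (m * n <= 400 && !has_ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, m, n),
                        1 - stats::pwilcox(U - 1, m, n)))
  } else {
    N <- m + n
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (U - m * n / 2) / sigma
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p_value = p, cliffs_delta = delta, n_x = m, n_y = n)
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counting one half; computed from midranks,
#' equal to the Mann-Whitney statistic normalized by `n_pos * n_neg`.
#'
#' @param scores Numeric scores (missing values removed with their labels).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise Pearson correlation matrix
#'
#' Each entry is computed on the complete cases of that feature pair;
#' the diagonal is 1. Zero-variance features yield missing entries for
#' their rows and columns and are listed in the `degenerate` attribute.
#'
#' @param features A data frame or named numeric matrix (columns =
#'   features), at least two columns.
#' @return Symmetric correlation matrix with a `degenerate` attribute.
#' @export
pearson_matrix <- function(features) {
  X <- as.matrix(features)
  if (ncol(X) < 2) rlang::abort("need at least 2 features")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  degen <- colnames(X)[is.na(sds) | sds == 0]
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diag(C) <- 1
  attr(C, "degenerate") <- degen
  C
}
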