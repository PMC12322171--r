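# deterministic miniature fixtures used across test files

tiny_matrix <- function(values, genes, samples, layer = "protein") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  omics_matrix(m, layer)
}

# a hand-built 2-gene, 8-sample cohort with a known loss effect on G1:
# G1 protein drops by exactly `drop` in lost samples (calls -1)
tiny_cohort <- function(drop = 1, n = 40, seed = 42) {
  set.seed(seed)
  genes <- c("G1", "G2")
  ids <- sprintf("s%02d", seq_len(n))
  calls <- matrix(0L, 2, n, dimnames = list(genes, ids))
  calls["G1", seq_len(n / 2)] <- -1L
  prot <- matrix(stats::rnorm(2 * n, 5, 0.1), 2, n,
                 dimnames = list(genes, ids))
  prot["G1", ] <- prot["G1", ] + drop * (calls["G1", ] == -1L) * -1
  samples <- tibble::tibble(sample_id = ids, study = "study_a")
  align_cohort(omics_matrix(prot, "protein"), NULL,
               copy_state_matrix(calls), samples,
               screen_config(min_study_size = 1))
}

# hypergeometric two-sided p by full enumeration (point-probability rule)
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  ks <- max(0, k - n_):min(m, k)
  probs <- choose(m, ks) * choose(n_, k - ks) / choose(m + n_, k)
  obs <- choose(m, a) * choose(n_, k - a) / choose(m + n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# t-distribution two-sided p via the incomplete-beta closed form,
# independent of the fitting path
beta_t_p <- function(t, df) stats::pbeta(df / (df + t^2), df / 2, 0.5)

# independent normal-equations OLS oracle
ols_oracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- unname(sqrt(diag(XtXi) * s2))
  tstat <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t = tstat,
       p = beta_t_p(tstat, df), df = df)
}
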