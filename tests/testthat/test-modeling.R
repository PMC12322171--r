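test_that("AUC ranking inverts negative predictors", {
  set.seed(6)
  n <- 200
  labels <- rbinom(n, 1, 0.5)
  feats <- tibble::tibble(
    good = labels + rnorm(n, 0, 0.8),
    bad = -labels + rnorm(n, 0, 0.8),   # negative predictor
    noise = rnorm(n),
    perfect = labels)
  r <- feature_auc_ranking(feats, labels)
  expect_equal(r$feature[1], "perfect")
  expect_equal(r$auc[r$feature == "perfect"], 1)
  expect_false(r$inverted[r$feature == "perfect"])
  expect_true(r$inverted[r$feature == "bad"])
  expect_true(all(r$auc >= 0.5))
  # inversion symmetry: reported AUC of an inverted feature is 1 - raw
  raw <- rank_auc(feats$bad, labels)
  expect_equal(r$auc[r$feature == "bad"], 1 - raw, tolerance = 1e-12)
  expect_error(feature_auc_ranking(feats, rep(1, n)), "both classes")
})

prep_fixture <- function(seed = 20, n_pairs = 80) {
  sim <- generate_cohort(generator_config(n_samples = 240, n_studies = 3,
                                          n_genes = 4 * n_pairs + 40,
                                          n_pairs = n_pairs,
                                          effect_size_delta = 1.5,
                                          sd_protein = 0.2, seed = seed))
  cfg <- screen_config(min_study_size = 1)
  fp <- filter_pairs(sim$pairs, sim$cohort, cfg)
  scr <- suppressMessages(run_screen(sim$cohort, fp$pairs, "protein", cfg))
  ft <- generate_feature_tables(sim$pairs, sim$truth,
                                generator_config(seed = seed))
  net <- gene_network(ft$edges)
  assemble_features(fp$pairs, scr, net, ft$essentiality, ft$complexes,
                    ft$gene_features, ft$pair_extras)$features
}

test_that("prepare_design z-scores, aggregates lengths, drops high-missing", {
  features <- prep_fixture()
  prep <- prepare_design(features, "compensation", min_cases = 20)
  expect_true("mean_paralog_length" %in% colnames(prep$design))
  expect_false(any(c("length_lost", "length_responder", "half_life") %in%
                     colnames(prep$design)))
  expect_true("half_life" %in% prep$dropped_features)
  # continuous columns standardized on the analysis set
  cont <- "mean_paralog_length"
  expect_equal(mean(prep$design[, cont]), 0, tolerance = 1e-10)
  expect_equal(sd(prep$design[, cont]), 1, tolerance = 1e-10)
  # collateral-loss rows removed for the compensation task
  expect_equal(prep$n_complete_cases, nrow(prep$design))
  expect_error(prepare_design(features[1:10, ], "compensation"),
               "complete cases")
})

test_that("lasso selection is null on noise and finds planted predictors", {
  set.seed(14)
  for (s in 1:5) {
    n <- 400
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("noise", 1:5)))
    y <- rbinom(n, 1, 0.3)
    expect_length(lasso_select(X, y, penalty_c = 0.01), 0)
  }
  # one strong predictor (log-odds slope 2) among noise, n = 2000
  set.seed(15)
  n <- 2000
  X <- cbind(signal = rnorm(n),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  y <- rbinom(n, 1, plogis(-0.5 + 2 * X[, "signal"]))
  sel <- lasso_select(X, y, penalty_c = 0.01)
  expect_true("signal" %in% sel)
  # independent check: the selected model's slope agrees with glm
  expect_gt(coef(glm(y ~ X[, "signal"], family = binomial()))[2], 1.5)
  # determinism of the convex problem
  expect_identical(sel, lasso_select(X, y, penalty_c = 0.01))
})

test_that("weaker shrinkage never shrinks the selected set", {
  set.seed(22)
  n <- 600
  X <- cbind(s1 = rnorm(n), s2 = rnorm(n),
             n1 = rnorm(n), n2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X[, "s1"] + 0.6 * X[, "s2"]))
  cs <- c(0.001, 0.01, 0.1, 1)
  sels <- lapply(cs, function(cc) lasso_select(X, y, penalty_c = cc))
  for (i in seq_len(length(cs) - 1)) {
    expect_true(all(sels[[i]] %in% sels[[i + 1]]))
  }
})

test_that("a saturated single-flag logistic model reproduces the 2x2 OR", {
  # counts a=20 (y=1,x=1), b=10 (y=1,x=0), c=10 (y=0,x=1), d=20 (y=0,x=0)
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  y <- rep(c(1, 0), c(30, 30))
  X <- cbind(flag = x)
  rep_ <- fit_final_model(X, y, "flag")
  or <- rep_$coefficients$odds_ratio[rep_$coefficients$term == "flag"]
  expect_equal(or, 4.0, tolerance = 1e-6)
  expect_equal(or, exact_2x2(20, 10, 10, 20)$odds_ratio, tolerance = 1e-6)
  # zero coefficient maps to OR 1
  expect_equal(exp(0), 1)
  # CI bounds follow exp(beta +/- 1.96 se)
  co <- rep_$coefficients[rep_$coefficients$term == "flag", ]
  expect_equal(co$ci_low, exp(co$estimate - 1.96 * co$std.error))
  expect_equal(co$ci_high, exp(co$estimate + 1.96 * co$std.error))
})

test_that("the final model reports both AUCs and flags separation", {
  features <- prep_fixture(seed = 23)
  prep <- prepare_design(features, "compensation", min_cases = 20)
  sel <- lasso_select(prep$design, prep$labels, penalty_c = 0.01)
  if (length(sel) == 0) sel <- prep$auc_ranking$feature[1]
  rep_ <- fit_final_model(prep$design, prep$labels, sel)
  expect_true(rep_$auc_selected >= 0.5 && rep_$auc_selected <= 1)
  expect_lte(rep_$auc_selected, rep_$auc_full + 0.02)
  expect_equal(rep_$n_complete_cases, prep$n_complete_cases)
  # perfect separation flag on a separable toy
  Xs <- cbind(sep = c(rnorm(30, -3), rnorm(30, 3)))
  ys <- rep(c(0, 1), each = 30)
  rep_s <- fit_final_model(Xs, ys, "sep")
  expect_true(rep_s$separation_flag)
})

test_that("the SL-augmented model uses exactly five predictors", {
  features <- prep_fixture(seed = 25)
  prep <- prepare_design(features, "compensation", min_cases = 20,
                         high_missing_cutoff = 0.4)
  stopifnot("synthetic_lethal_flag" %in% colnames(prep$design))
  sl <- prep$design[, "synthetic_lethal_flag"]
  rep_ <- sl_augmented_model(
    prep$design[, setdiff(colnames(prep$design), "synthetic_lethal_flag")],
    prep$labels, sl)
  expect_setequal(
    rep_$selected_features,
    c("synthetic_lethal", "family_size", "degree_centrality_lost",
      "neighbour_essentiality_lost", "jaccard"))
  expect_equal(nrow(rep_$coefficients), 6)  # intercept + 5
  expect_error(sl_augmented_model(prep$design[, "jaccard", drop = FALSE],
                                  prep$labels, sl),
               "lacks predictor")
})

test_that("tidiers expose model and fit summaries as tibbles", {
  x <- rnorm(40)
  fit <- ols_fit(1 + x + rnorm(40, 0, 0.1), cbind(intercept = 1, x = x))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("intercept", "x"))
  gl <- glance(fit)
  expect_equal(gl$df.residual, 38)
  X <- cbind(f = rbinom(80, 1, 0.5))
  y <- rbinom(80, 1, 0.4)
  mr <- fit_final_model(X, y, "f")
  expect_s3_class(tidy(mr), "tbl_df")
  expect_true(all(c("auc_selected", "n_complete_cases") %in%
                    names(glance(mr))))
})
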