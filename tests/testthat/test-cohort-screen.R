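make_pairs <- function(...) {
  tibble::tibble(...)
}

test_that("pair filters apply boundary rules in order with a ledger", {
  sim <- generate_cohort(generator_config(n_samples = 100, n_studies = 2,
                                          n_genes = 40, n_pairs = 8,
                                          missing_rate = 0, seed = 3))
  pairs <- sim$pairs
  pairs$sequence_identity <- c(0.20, 0.21, rep(0.5, 6))  # 0.20 excluded
  pairs$family_size <- c(3, 3, 20, 19, rep(3, 4))        # 20 excluded
  pairs$chromosome_a[5] <- pairs$chromosome_b[5] <- "17" # same chr excluded
  fp <- filter_pairs(pairs, sim$cohort, screen_config(min_study_size = 1))
  expect_equal(fp$ledger$removed[fp$ledger$rule == "identity"], 1)
  expect_equal(fp$ledger$removed[fp$ledger$rule == "family_size"], 1)
  expect_equal(fp$ledger$removed[fp$ledger$rule == "same_chromosome"], 1)
  expect_equal(nrow(fp$pairs), 5)
  # same-chromosome filter can be switched off
  fp2 <- filter_pairs(pairs, sim$cohort,
                      screen_config(min_study_size = 1,
                                    exclude_same_chromosome = FALSE))
  expect_equal(nrow(fp2$pairs), 6)
})

test_that("coverage filter removes sparsely observed proteins", {
  sim <- generate_cohort(generator_config(n_samples = 100, n_studies = 2,
                                          n_genes = 40, n_pairs = 8,
                                          missing_rate = 0, seed = 3))
  prot <- unclass(sim$cohort$protein)
  prot[sim$pairs$gene_a[1], 1:60] <- NA  # 40% coverage < 50%
  cohort <- sim$cohort
  cohort$protein <- omics_matrix(prot, "protein")
  fp <- filter_pairs(sim$pairs, cohort, screen_config(min_study_size = 1))
  expect_false(sim$pairs$gene_a[1] %in%
                 c(fp$pairs$gene_a, fp$pairs$gene_b))
  expect_equal(fp$ledger$removed[fp$ledger$rule == "coverage"], 1)
})

test_that("loss eligibility needs 20 lost and 20 quantified-lost samples", {
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  genes <- c("g19", "g25", "gok")
  calls <- matrix(0L, 3, n, dimnames = list(genes, ids))
  calls["g19", 1:19] <- -1L
  calls["g25", 1:25] <- -1L
  calls["gok", 1:30] <- -1L
  set.seed(1)
  prot <- matrix(rnorm(3 * n, 5, 0.2), 3, n, dimnames = list(genes, ids))
  prot["g25", 1:7] <- NA  # only 18 of 25 lost samples quantified
  prot["gok", ] <- prot["gok", ] - 0.5 * (calls["gok", ] == -1L)
  cohort <- align_cohort(omics_matrix(prot, "protein"), NULL,
                         copy_state_matrix(calls),
                         tibble::tibble(sample_id = ids, study = "a"),
                         screen_config(min_study_size = 1))
  ann <- annotate_losses(cohort, genes, screen_config(min_study_size = 1))
  expect_false(ann$eligible[ann$gene == "g19"])
  expect_false(ann$eligible[ann$gene == "g25"])
  expect_equal(ann$n_lost_with_protein[ann$gene == "g25"], 18)
  expect_true(ann$validated[ann$gene == "gok"])
  expect_lt(ann$validation_coefficient[ann$gene == "gok"], 0)
})

test_that("loss validation recovers a planted drop at low noise", {
  set.seed(7)
  n <- 200; ids <- sprintf("s%03d", 1:n)
  calls <- matrix(0L, 1, n, dimnames = list("g", ids))
  calls[1, 1:40] <- -1L
  prot <- matrix(rnorm(n, 8, 0.15) - 0.5 * (calls[1, ] == -1L), 1, n,
                 dimnames = list("g", ids))
  cohort <- align_cohort(omics_matrix(prot, "protein"), NULL,
                         copy_state_matrix(calls),
                         tibble::tibble(sample_id = ids,
                                        study = rep(c("a", "b"), n / 2)),
                         screen_config(min_study_size = 1))
  ann <- annotate_losses(cohort, "g", screen_config(min_study_size = 1))
  expect_true(ann$validated)
  expect_equal(ann$validation_coefficient, -0.5, tolerance = 0.1)
})

test_that("the pair regression matches an independent OLS oracle", {
  set.seed(13)
  n <- 150; ids <- sprintf("s%03d", 1:n)
  genes <- c("lost", "resp")
  calls <- matrix(0L, 2, n, dimnames = list(genes, ids))
  calls["lost", sample(n, 45)] <- -1L
  calls["resp", sample(n, 20)] <- 1L
  study <- rep(c("a", "b", "c"), length.out = n)
  prot <- matrix(rnorm(2 * n, 5, 0.5), 2, n, dimnames = list(genes, ids))
  prot["resp", ] <- prot["resp", ] + 0.4 * (calls["lost", ] == -1L) +
    0.2 * (study == "b")
  prot["lost", ] <- prot["lost", ] - 0.6 * (calls["lost", ] == -1L)
  cohort <- align_cohort(omics_matrix(prot, "protein"), NULL,
                         copy_state_matrix(calls),
                         tibble::tibble(sample_id = ids, study = study),
                         screen_config(min_study_size = 1))
  pairs <- make_pairs(gene_a = "resp", gene_b = "lost",
                      sequence_identity = 0.6, family_size = 2,
                      chromosome_a = "1", chromosome_b = "2")
  scr <- run_screen(cohort, pairs, "protein",
                    screen_config(min_study_size = 1))
  row <- scr[scr$lost_gene == "lost", ]
  # oracle: explicit design on the same sample restriction
  keep <- calls["lost", ] %in% c(-1L, 0L)
  X <- cbind(intercept = 1, loss = as.numeric(calls["lost", keep] == -1L),
             study_b = as.numeric(study[keep] == "b"),
             study_c = as.numeric(study[keep] == "c"),
             responder_cn = as.numeric(calls["resp", keep]))
  oracle <- ols_oracle(prot["resp", keep], X)
  expect_equal(row$coefficient, oracle$beta[2], tolerance = 1e-8)
  expect_equal(row$p, oracle$p[2], tolerance = 1e-8)
})

test_that("noise-free loss effects are recovered exactly and classified", {
  n <- 60; ids <- sprintf("s%02d", 1:n)
  genes <- c("L", "R")
  calls <- matrix(0L, 2, n, dimnames = list(genes, ids))
  calls["L", 1:25] <- -1L
  prot <- matrix(0, 2, n, dimnames = list(genes, ids))
  prot["R", ] <- 1 + 0.5 * (calls["L", ] == -1L)
  prot["L", ] <- 5 - (calls["L", ] == -1L)
  cohort <- align_cohort(omics_matrix(prot, "protein"), NULL,
                         copy_state_matrix(calls),
                         tibble::tibble(sample_id = ids, study = "a"),
                         screen_config(min_study_size = 1))
  pairs <- make_pairs(gene_a = "R", gene_b = "L",
                      sequence_identity = 0.6, family_size = 2,
                      chromosome_a = "1", chromosome_b = "2")
  scr <- run_screen(cohort, pairs, "protein",
                    screen_config(min_study_size = 1))
  row <- scr[scr$lost_gene == "L" & scr$responder_gene == "R", ]
  expect_equal(row$coefficient, 0.5, tolerance = 1e-10)
  expect_equal(row$class, "compensation")
})

test_that("hit classes are mutually exclusive and require both thresholds", {
  sim <- generate_cohort(generator_config(n_samples = 240, n_studies = 3,
                                          n_genes = 200, n_pairs = 40,
                                          seed = 17))
  fp <- filter_pairs(sim$pairs, sim$cohort,
                     screen_config(min_study_size = 1))
  scr <- suppressMessages(run_screen(sim$cohort, fp$pairs, "protein",
                                     screen_config(min_study_size = 1)))
  hits <- scr[scr$testable & scr$class != "none", ]
  expect_true(all(hits$fdr < 0.05 & hits$p < 0.05))
  expect_true(all((hits$class == "compensation") ==
                    (hits$coefficient > 0)))
})

test_that("residuals vanish on exact linear protein-mRNA relationships", {
  n <- 90; ids <- sprintf("s%02d", 1:n)
  study <- rep(c("a", "b", "c"), each = n / 3)
  set.seed(5)
  mr <- matrix(rnorm(2 * n, 5, 1), 2, n, dimnames = list(c("g1", "g2"), ids))
  # protein = 2*mRNA + 3 within each study (study-specific intercepts)
  offs <- c(a = 3, b = 4, c = 2)
  pr <- 2 * mr + matrix(rep(offs[study], each = 2), 2, n)
  dimnames(pr) <- dimnames(mr)
  res <- make_residuals(omics_matrix(pr, "protein"),
                        omics_matrix(mr, "mrna"),
                        tibble::tibble(sample_id = ids, study = study),
                        screen_config(min_paired_samples = 10))
  expect_lt(max(abs(unclass(res))), 1e-10)
})

test_that("residuals are orthogonal to study indicators and corrected mRNA", {
  n <- 120; ids <- sprintf("s%03d", 1:n)
  study <- rep(c("a", "b", "c"), each = n / 3)
  set.seed(9)
  mr <- matrix(rnorm(n, 5, 1), 1, n, dimnames = list("g", ids))
  pr <- 1.5 * mr + matrix(rnorm(n, 0, 0.5), 1, n)
  dimnames(pr) <- dimnames(mr)
  res <- make_residuals(omics_matrix(pr, "protein"),
                        omics_matrix(mr, "mrna"),
                        tibble::tibble(sample_id = ids, study = study),
                        screen_config(min_paired_samples = 10))
  r <- unclass(res)["g", ]
  for (s in unique(study)) {
    expect_lt(abs(sum(r[study == s])), 1e-8)
  }
  oh <- cbind(1, as.numeric(study == "b"), as.numeric(study == "c"))
  corrected_m <- mr[1, ] - oh %*% solve(crossprod(oh), crossprod(oh, mr[1, ]))
  expect_lt(abs(sum(r * corrected_m)), 1e-8)
})

test_that("two-stage residuals equal an explicit projection oracle", {
  n <- 45; ids <- sprintf("s%02d", 1:n)
  study <- rep(c("a", "b", "c"), each = 15)
  set.seed(31)
  mr <- matrix(rnorm(n, 6, 1), 1, n, dimnames = list("g", ids))
  pr <- 0.8 * mr + matrix(rnorm(n, 0, 0.3), 1, n)
  dimnames(pr) <- dimnames(mr)
  res <- make_residuals(omics_matrix(pr, "protein"),
                        omics_matrix(mr, "mrna"),
                        tibble::tibble(sample_id = ids, study = study),
                        screen_config(min_paired_samples = 10))
  # oracle: project protein off the column space of [study one-hots,
  # study-corrected mRNA]
  S <- stats::model.matrix(~ factor(study))
  P <- function(M) M %*% solve(crossprod(M), t(M))
  m_corr <- as.numeric((diag(n) - P(S)) %*% mr[1, ])
  Z <- cbind(S, m_corr)
  oracle <- as.numeric((diag(n) - P(Z)) %*% pr[1, ])
  expect_equal(unname(unclass(res)["g", ]), oracle, tolerance = 1e-8)
})

test_that("mechanism calls follow the layer-overlap rules", {
  base <- tibble::tibble(
    lost_gene = c("a", "b", "c", "d"), responder_gene = c("x", "y", "z", "w"),
    class = "none")
  pr <- base; pr$class <- c("compensation", "compensation", "none",
                            "compensation")
  mr <- base; mr$class <- c("compensation", "none", "none", "compensation")
  re <- base; re$class <- c("none", "compensation", "none", "compensation")
  mech <- classify_mechanism(pr, mr, re)
  g <- function(l) mech$mechanism[mech$lost_gene == l]
  expect_equal(g("a"), "transcriptional")       # mRNA hit, no residual
  expect_equal(g("b"), "post_transcriptional")  # residual hit, no mRNA
  expect_equal(g("c"), "none")
  expect_equal(g("d"), "both_layers")
  expect_error(classify_mechanism(pr, mr[1:2, ], re), "different pair sets")
})

test_that("symmetric-pair counts match brute-force enumeration", {
  rows <- tibble::tibble(
    lost_gene = c("a", "b", "a", "c", "b", "d", "c", "d"),
    responder_gene = c("b", "a", "c", "a", "d", "b", "d", "c"),
    class = c("compensation", "compensation", "compensation", "none",
              "none", "none", "collateral_loss", "none"),
    testable = TRUE)
  out <- symmetric_analysis(rows)
  comp <- out[out$class == "compensation", ]
  # pairs: ab (both comp), ac (one comp), bd (none), cd (one CL)
  expect_equal(comp$both_hit, 1)
  expect_equal(comp$dir1_only + comp$dir2_only, 1)
  expect_equal(comp$neither, 2)
  cl <- out[out$class == "collateral_loss", ]
  expect_equal(cl$both_hit, 0)
  expect_equal(cl$dir1_only + cl$dir2_only, 1)
  expect_true(all(c("odds_ratio", "p") %in% names(out)))

  uni <- rows[c(1, 3, 5), ]
  expect_warning(empty <- symmetric_analysis(uni), "both directions")
  expect_equal(nrow(empty), 0)
})
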