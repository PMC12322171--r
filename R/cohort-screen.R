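#' Filter paralog pairs to a testable set
#'
#' Applies the pair-selection rules in order: sequence identity at or below
#' `identity_min_exclusive` excluded; family size at or above
#' `family_size_max_exclusive` excluded; either protein observed in fewer
#' than `coverage_fraction` of cohort samples excluded; both members on the
#' same chromosome excluded (when the flag is on). An exclusion ledger
#' records the count removed by each rule.
#'
#' @param pairs Annotated pair table (see [read_pair_table()]).
#' @param cohort A `matched_cohort`.
#' @param cfg A [screen_config()].
#' @return A list: `pairs` (surviving unordered pairs) and `ledger`
#'   (tibble: `rule`, `removed`, `remaining`).
#' @export
filter_pairs <- function(pairs, cohort, cfg = screen_config()) {
  prot <- unclass(cohort$protein)
  n_samp <- ncol(prot)
  frac_obs <- rowMeans(!is.na(prot))
  coverage <- function(g) {
    ifelse(g %in% rownames(prot), frac_obs[g], 0)
  }
  steps <- list(
    identity = function(df)
      df$sequence_identity > cfg$identity_min_exclusive,
    family_size = function(df)
      df$family_size < cfg$family_size_max_exclusive,
    coverage = function(df)
      coverage(df$gene_a) >= cfg$coverage_fraction &
      coverage(df$gene_b) >= cfg$coverage_fraction,
    same_chromosome = function(df)
      if (cfg$exclude_same_chromosome)
        df$chromosome_a != df$chromosome_b else rep(TRUE, nrow(df))
  )
  ledger <- tibble::tibble(rule = character(), removed = integer(),
                           remaining = integer())
  cur <- pairs
  for (rule in names(steps)) {
    keep <- steps[[rule]](cur)
    ledger <- dplyr::bind_rows(ledger, tibble::tibble(
      rule = rule, removed = sum(!keep), remaining = sum(keep)))
    cur <- cur[keep, ]
  }
  list(pairs = tibble::as_tibble(cur), ledger = ledger)
}

one_hot_studies <- function(study) {
  levels <- sort(unique(study))
  ref <- levels[1]
  cols <- lapply(setdiff(levels, ref), function(l) as.numeric(study == l))
  if (length(cols) == 0) {
    return(matrix(numeric(0), nrow = length(study), ncol = 0))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("study_", setdiff(levels, ref))
  m
}

#' Annotate and validate hemizygous gene losses
#'
#' For every requested gene, collects the samples where the copy-number
#' call is -1 (hemizygous loss). A gene is *eligible* when it is lost in at
#' least `min_lost_samples` samples and its protein is quantified in at
#' least `min_lost_samples` of those. Eligible genes are *validated* by an
#' OLS fit of protein abundance on the loss indicator plus study one-hots
#' (restricted to samples with call in \{-1, 0\}): validation requires a
#' nominally significant (p below `p_threshold`) negative loss coefficient,
#' i.e. loss of the gene measurably lowers its own protein.
#'
#' @param cohort A `matched_cohort`.
#' @param genes Genes to annotate (default: all genes of the copy-number
#'   layer). Genes absent from the copy-number layer are skipped with a
#'   message.
#' @param cfg A [screen_config()].
#' @return A tibble: `gene`, `n_lost`, `n_lost_with_protein`,
#'   `eligible`, `validation_coefficient`, `validation_p`, `validated`.
#' @export
annotate_losses <- function(cohort, genes = rownames(cohort$cn),
                            cfg = screen_config()) {
  cn <- unclass(cohort$cn)
  prot <- unclass(cohort$protein)
  study <- cohort$samples$study[match(colnames(prot), cohort$samples$sample_id)]
  studies_oh <- one_hot_studies(study)
  missing_genes <- setdiff(genes, rownames(cn))
  if (length(missing_genes) > 0) {
    rlang::inform(sprintf("%d gene(s) absent from copy-number layer, skipped",
                          length(missing_genes)))
    genes <- setdiff(genes, missing_genes)
  }
  purrr::map(genes, function(g) {
    calls <- cn[g, ]
    lost <- !is.na(calls) & calls == -1L
    has_prot <- g %in% rownames(prot)
    obs <- if (has_prot) !is.na(prot[g, ]) else rep(FALSE, ncol(cn))
    n_lost <- sum(lost)
    n_lp <- sum(lost & obs)
    eligible <- has_prot && n_lost >= cfg$min_lost_samples &&
      n_lp >= cfg$min_lost_samples
    out <- tibble::tibble(gene = g, n_lost = n_lost,
                          n_lost_with_protein = n_lp, eligible = eligible,
                          validation_coefficient = NA_real_,
                          validation_p = NA_real_, validated = FALSE)
    if (!eligible) return(out)
    keep <- !is.na(calls) & calls %in% c(-1L, 0L) & obs
    design <- cbind(intercept = 1, loss = as.numeric(calls[keep] == -1L),
                    studies_oh[keep, , drop = FALSE])
    fit <- ols_fit(prot[g, keep], design)
    out$validation_coefficient <- unname(fit$coefficients["loss"])
    out$validation_p <- unname(fit$p_values["loss"])
    out$validated <- !is.na(out$validation_p) &&
      out$validation_p < cfg$p_threshold && out$validation_coefficient < 0
    out
  }) |> purrr::list_rbind()
}

# Directed loss-response regression for one (lost, responder) pair on one
# layer. Residual layer omits the study and self-copy-number covariates
# (already regressed out of the residual values).
test_pair_row <- function(lost_gene, responder_gene, layer_matrix, layer,
                          cn, study, studies_oh, cfg) {
  base <- tibble::tibble(
    lost_gene = lost_gene, responder_gene = responder_gene, layer = layer,
    n_loss = NA_integer_, n_neutral = NA_integer_,
    coefficient = NA_real_, t = NA_real_, p = NA_real_,
    testable = FALSE)
  if (!responder_gene %in% rownames(layer_matrix) ||
      !lost_gene %in% rownames(cn)) {
    return(base)
  }
  calls <- cn[lost_gene, ]
  vals <- layer_matrix[responder_gene, ]
  keep <- !is.na(calls) & calls %in% c(-1L, 0L) & !is.na(vals)
  loss <- as.numeric(calls[keep] == -1L)
  if (layer == "residual") {
    design <- cbind(intercept = 1, loss = loss)
  } else {
    resp_cn <- if (responder_gene %in% rownames(cn)) {
      as.numeric(cn[responder_gene, keep])
    } else {
      rep(0, sum(keep))
    }
    design <- cbind(intercept = 1, loss = loss,
                    studies_oh[keep, , drop = FALSE],
                    responder_cn = resp_cn)
  }
  y <- vals[keep]
  ok <- stats::complete.cases(design)
  design <- design[ok, , drop = FALSE]
  y <- y[ok]
  loss <- loss[ok]
  n_loss <- sum(loss == 1)
  n_neutral <- sum(loss == 0)
  base$n_loss <- n_loss
  base$n_neutral <- n_neutral
  if (n_loss < cfg$min_lost_samples || n_neutral < 2) return(base)
  fit <- ols_fit(y, design)
  if (!"loss" %in% names(fit$coefficients)) return(base)
  base$coefficient <- unname(fit$coefficients["loss"])
  base$t <- unname(fit$t_statistics["loss"])
  base$p <- unname(fit$p_values["loss"])
  base$testable <- TRUE
  base
}

#' Run the cohort loss-response screen on one data layer
#'
#' For every testable unordered pair, tests up to two directed hypotheses
#' (loss of A2 affecting A1, and vice versa), each requiring the lost gene
#' to be a validated loss (protein-layer validation gates all layers). The
#' model explains the responder's abundance by the binary loss indicator,
#' study one-hots, and the responder's own thresholded copy-number call
#' (covariates omitted on the residual layer). Samples with amplification
#' or homozygous deletion of the lost gene are excluded. Benjamini-Hochberg
#' adjustment pools all testable rows of the layer; hits require FDR and
#' uncorrected p below threshold, classed `compensation` (positive
#' coefficient) or `collateral_loss` (negative).
#'
#' @param cohort A `matched_cohort`.
#' @param testable_pairs Surviving pairs from [filter_pairs()].
#' @param layer `"protein"`, `"mrna"`, or `"residual"`.
#' @param cfg A [screen_config()].
#' @param loss_annotations Output of [annotate_losses()]; computed on the
#'   protein layer if omitted.
#' @param residual_matrix The residual `omics_matrix` from
#'   [make_residuals()], required when `layer = "residual"`.
#' @return A `screen_result` tibble: `lost_gene`, `responder_gene`,
#'   `layer`, `n_loss`, `n_neutral`, `coefficient`, `t`, `p`, `fdr`,
#'   `class`, `testable`.
#' @export
run_screen <- function(cohort, testable_pairs,
                       layer = c("protein", "mrna", "residual"),
                       cfg = screen_config(),
                       loss_annotations = NULL,
                       residual_matrix = NULL) {
  layer <- match.arg(layer)
  layer_matrix <- switch(layer,
    protein = cohort$protein,
    mrna = {
      if (is.null(cohort$mrna)) rlang::abort("cohort has no mRNA layer")
      cohort$mrna
    },
    residual = {
      if (is.null(residual_matrix)) {
        rlang::abort("residual layer requires residual_matrix")
      }
      residual_matrix
    })
  if (is.null(loss_annotations)) {
    cand <- unique(c(testable_pairs$gene_a, testable_pairs$gene_b))
    loss_annotations <- annotate_losses(
      cohort, genes = intersect(cand, rownames(cohort$cn)), cfg)
  }
  validated <- loss_annotations$gene[loss_annotations$validated]
  directed <- dplyr::bind_rows(
    tibble::tibble(lost_gene = testable_pairs$gene_b,
                   responder_gene = testable_pairs$gene_a),
    tibble::tibble(lost_gene = testable_pairs$gene_a,
                   responder_gene = testable_pairs$gene_b)
  ) |>
    dplyr::filter(.data$lost_gene %in% validated) |>
    dplyr::arrange(.data$lost_gene, .data$responder_gene)
  if (nrow(directed) == 0) {
    rlang::warn("no testable directed pairs (no validated losses)")
    res <- tibble::tibble(lost_gene = character(),
                          responder_gene = character(), layer = character(),
                          n_loss = integer(), n_neutral = integer(),
                          coefficient = numeric(), t = numeric(),
                          p = numeric(), fdr = numeric(), class = character(),
                          testable = logical())
    return(structure(res, class = c("screen_result", class(res))))
  }
  cn <- unclass(cohort$cn)
  lm_ <- unclass(layer_matrix)
  study <- cohort$samples$study[
    match(colnames(lm_), cohort$samples$sample_id)]
  studies_oh <- one_hot_studies(study)
  rows <- purrr::map2(directed$lost_gene, directed$responder_gene,
                      ~ test_pair_row(.x, .y, lm_, layer, cn, study,
                                      studies_oh, cfg)) |>
    purrr::list_rbind()
  rows$fdr <- NA_real_
  rows$fdr[rows$testable] <- bh_adjust(rows$p[rows$testable])
  rows <- rows |>
    dplyr::mutate(class = dplyr::case_when(
      !.data$testable ~ NA_character_,
      .data$fdr < cfg$fdr_threshold & .data$p < cfg$p_threshold &
        .data$coefficient > 0 ~ "compensation",
      .data$fdr < cfg$fdr_threshold & .data$p < cfg$p_threshold &
        .data$coefficient < 0 ~ "collateral_loss",
      TRUE ~ "none"
    ))
  structure(rows, class = c("screen_result", setdiff(class(rows),
                                                     "screen_result")),
            layer = layer)
}

#' Symmetric-pair enrichment
#'
#' Among unordered pairs tested in both directions, asks whether a hit in
#' one direction makes a hit in the other direction more likely, separately
#' for compensation and collateral loss, via an exact 2x2 test. Direction 1
#' is fixed as the one whose lost gene sorts first.
#'
#' @param rows A `screen_result`.
#' @return A tibble: `class`, `both_hit`, `dir1_only`, `dir2_only`,
#'   `neither`, `odds_ratio`, `p`, or an empty tibble with a warning when
#'   no pair was tested bidirectionally.
#' @export
symmetric_analysis <- function(rows) {
  tested <- rows |> dplyr::filter(.data$testable)
  tested <- tested |>
    dplyr::mutate(lo = pmin(.data$lost_gene, .data$responder_gene),
                  hi = pmax(.data$lost_gene, .data$responder_gene),
                  dir1 = .data$lost_gene == .data$lo)
  both <- tested |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::ungroup()
  if (nrow(both) == 0) {
    rlang::warn("no unordered pair was tested in both directions")
    return(tibble::tibble(class = character(), both_hit = integer(),
                          dir1_only = integer(), dir2_only = integer(),
                          neither = integer(), odds_ratio = numeric(),
                          p = numeric()))
  }
  purrr::map(c("compensation", "collateral_loss"), function(cl) {
    wide <- both |>
      dplyr::mutate(hit = .data$class == cl,
                    dir = ifelse(.data$dir1, "h1", "h2")) |>
      dplyr::select("lo", "hi", "dir", "hit") |>
      tidyr::pivot_wider(names_from = "dir", values_from = "hit")
    a <- sum(wide$h1 & wide$h2); b <- sum(wide$h1 & !wide$h2)
    c_ <- sum(!wide$h1 & wide$h2); d <- sum(!wide$h1 & !wide$h2)
    ft <- exact_2x2(a, b, c_, d)
    tibble::tibble(class = cl, both_hit = a, dir1_only = b, dir2_only = c_,
                   neither = d, odds_ratio = ft$odds_ratio, p = ft$p_value)
  }) |> purrr::list_rbind()
}
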