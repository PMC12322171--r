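#' Preprocess a label-free quantification matrix
#'
#' Applies, in order: log2 transform of raw intensities; per-sample mean
#' centering (each sample's adjustment factor is its mean over observed
#' values minus the global mean over observed values); removal of proteins
#' observed in fewer than `min_obs_fraction` of samples; imputation of each
#' remaining missing cell with the lowest observed value of that sample's
#' column (a detection-limit proxy for left-censored missingness).
#'
#' The pre-imputation observation mask of the retained proteins is kept in
#' the `observed` attribute; "quantified" always means observed before
#' imputation.
#'
#' @param raw An `omics_matrix` of strictly positive raw intensities
#'   (missing allowed).
#' @param min_obs_fraction Minimum fraction of samples a protein must be
#'   observed in (default 0.2).
#' @return A preprocessed `omics_matrix` (log2 scale, no missing values)
#'   with an `observed` logical attribute matrix.
#' @export
preprocess_lfq <- function(raw, min_obs_fraction = 0.2) {
  m <- unclass(raw)
  obs <- !is.na(m)
  if (any(m[obs] <= 0)) {
    rlang::abort("raw intensities must be strictly positive where observed")
  }
  m <- log2(m)
  adj <- colMeans(m, na.rm = TRUE) - mean(m, na.rm = TRUE)
  m <- sweep(m, 2, adj, "-")
  frac_obs <- rowMeans(obs)
  keep <- frac_obs >= min_obs_fraction
  m <- m[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) {
      if (all(miss)) rlang::abort(sprintf(
        "sample %s has no observed values to impute from", colnames(m)[j]))
      m[miss, j] <- min(m[!miss, j])
    }
  }
  out <- omics_matrix(m, "protein")
  attr(out, "observed") <- obs
  out
}

observed_mask <- function(m) {
  attr(m, "observed") %||% !is.na(unclass(m))
}

#' Verify knockouts against the wild-type pool
#'
#' For every clone, runs a two-tailed pooled-variance t-test comparing the
#' targeted protein's abundance in the knockout replicates against the
#' wild-type replicates, followed by Benjamini-Hochberg adjustment across
#' all tested clones. A clone is `verified` when the drop is significant
#' (FDR and uncorrected p below the configured thresholds, negative mean
#' difference); `unquantified` when the target protein is absent from the
#' matrix or was never observed in a wild-type sample before imputation.
#'
#' @param matrix A preprocessed `omics_matrix` from [preprocess_lfq()].
#' @param design Design tibble: `clone_id`, `target_gene`, list-columns
#'   `ko_samples`, `wt_samples`.
#' @param cfg A [screen_config()].
#' @return A tibble: `clone_id`, `target_gene`, `status`,
#'   `mean_difference`, `t`, `p`, `fdr`.
#' @export
verify_knockouts <- function(matrix, design, cfg = screen_config()) {
  obs <- observed_mask(matrix)
  all_ids <- colnames(matrix)
  rows <- purrr::pmap(design, function(clone_id, target_gene, ko_samples,
                                       wt_samples, ...) {
    unknown <- setdiff(c(ko_samples, wt_samples), all_ids)
    if (length(unknown) > 0) {
      rlang::abort(sprintf("design for clone %s references unknown sample(s): %s",
                           clone_id, paste(unknown, collapse = ", ")))
    }
    if (length(intersect(ko_samples, wt_samples)) > 0) {
      rlang::abort(sprintf("clone %s: ko and wt samples overlap", clone_id))
    }
    base <- tibble::tibble(clone_id = clone_id, target_gene = target_gene)
    if (!target_gene %in% rownames(matrix) ||
        !any(obs[target_gene, wt_samples])) {
      return(dplyr::mutate(base, status = "unquantified",
                           mean_difference = NA_real_, t = NA_real_,
                           p = NA_real_))
    }
    tt <- pooled_t(unclass(matrix)[target_gene, ko_samples],
                   unclass(matrix)[target_gene, wt_samples])
    dplyr::mutate(base, status = "tested",
                  mean_difference = tt$mean_difference, t = tt$t,
                  p = tt$p_value)
  }) |> purrr::list_rbind()
  rows$fdr <- NA_real_
  tested <- rows$status == "tested"
  rows$fdr[tested] <- bh_adjust(rows$p[tested])
  rows |>
    dplyr::mutate(status = dplyr::case_when(
      .data$status == "unquantified" ~ "unquantified",
      .data$fdr < cfg$fdr_threshold & .data$p < cfg$p_threshold &
        .data$mean_difference < 0 ~ "verified",
      TRUE ~ "not_verified"
    ))
}

#' Test paralog responses in verified knockouts
#'
#' For each verified clone, compares the abundance of every paralog of the
#' targeted gene (knockout replicates vs wild-type pool, pooled-variance
#' t-test), pooling Benjamini-Hochberg adjustment across all
#' (clone, responder) tests jointly — a separate FDR pool from knockout
#' verification. Responders are paralogs of the target that pass the
#' identity and family-size filters (the same-chromosome filter is off by
#' default in the isogenic setting) and were observed in at least one
#' sample before imputation.
#'
#' @param matrix Preprocessed `omics_matrix`.
#' @param design Design tibble (see [verify_knockouts()]).
#' @param verifications Output of [verify_knockouts()].
#' @param pairs Annotated pair table (see [read_pair_table()]).
#' @param cfg A [screen_config()]; defaults keep same-chromosome pairs.
#' @return A tibble: `clone_id`, `lost_gene`, `responder_gene`,
#'   `mean_difference`, `t`, `p`, `fdr`, `class`.
#' @export
paralog_response_tests <- function(matrix, design, verifications, pairs,
                                   cfg = screen_config(
                                     exclude_same_chromosome = FALSE)) {
  verified <- verifications |> dplyr::filter(.data$status == "verified")
  if (nrow(verified) == 0) {
    rlang::warn("no verified knockouts; returning empty result")
    return(tibble::tibble(clone_id = character(), lost_gene = character(),
                          responder_gene = character(),
                          mean_difference = numeric(), t = numeric(),
                          p = numeric(), fdr = numeric(),
                          class = character()))
  }
  pairs_ok <- pairs |>
    dplyr::filter(.data$sequence_identity > cfg$identity_min_exclusive,
                  .data$family_size < cfg$family_size_max_exclusive)
  if (cfg$exclude_same_chromosome) {
    pairs_ok <- pairs_ok |>
      dplyr::filter(.data$chromosome_a != .data$chromosome_b)
  }
  obs <- observed_mask(matrix)
  rows <- purrr::pmap(verified, function(clone_id, target_gene, ...) {
    des <- design[design$clone_id == clone_id, ]
    responders <- unique(c(
      pairs_ok$gene_a[pairs_ok$gene_b == target_gene],
      pairs_ok$gene_b[pairs_ok$gene_a == target_gene]))
    responders <- responders[responders %in% rownames(matrix)]
    responders <- responders[rowSums(obs[responders, , drop = FALSE]) > 0]
    purrr::map(responders, function(g) {
      tt <- pooled_t(unclass(matrix)[g, des$ko_samples[[1]]],
                     unclass(matrix)[g, des$wt_samples[[1]]])
      tibble::tibble(clone_id = clone_id, lost_gene = target_gene,
                     responder_gene = g,
                     mean_difference = tt$mean_difference,
                     t = tt$t, p = tt$p_value)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (nrow(rows) == 0) {
    rlang::warn("no testable paralog responses")
    return(rows)
  }
  rows |>
    dplyr::mutate(
      fdr = bh_adjust(.data$p),
      class = dplyr::case_when(
        .data$fdr < cfg$fdr_threshold & .data$p < cfg$p_threshold &
          .data$mean_difference > 0 ~ "compensation",
        .data$fdr < cfg$fdr_threshold & .data$p < cfg$p_threshold &
          .data$mean_difference < 0 ~ "collateral_loss",
        TRUE ~ "none"
      ))
}
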