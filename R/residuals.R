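#' Build the protein residual layer
#'
#' Isolates post-transcriptional signal by removing, per gene, the part of
#' protein abundance explained by its own transcript. Two stages: first
#' both protein and mRNA are residualized on study one-hots (study may act
#' on the two layers differently), then study-corrected protein is
#' regressed on study-corrected mRNA (with intercept) and the residuals
#' kept. Each gene's residual row covers only samples where both its
#' protein and mRNA were observed; genes with fewer than
#' `cfg$min_paired_samples` paired observations are excluded.
#'
#' @param protein Protein `omics_matrix`.
#' @param mrna mRNA `omics_matrix`.
#' @param samples Sample table (`sample_id`, `study`).
#' @param cfg A [screen_config()]; uses `min_paired_samples`.
#' @return A residual-layer `omics_matrix` over the shared samples, `NA`
#'   outside each gene's paired coverage, with an `excluded_genes`
#'   attribute listing genes below the pairing minimum.
#' @export
make_residuals <- function(protein, mrna, samples, cfg = screen_config()) {
  ids <- intersect(colnames(protein), colnames(mrna))
  if (length(ids) < 2) rlang::abort("protein and mrna share too few samples")
  genes <- intersect(rownames(protein), rownames(mrna))
  if (length(genes) == 0) rlang::abort("no shared genes across layers")
  p <- unclass(protein)[genes, ids, drop = FALSE]
  m <- unclass(mrna)[genes, ids, drop = FALSE]
  study <- samples$study[match(ids, samples$sample_id)]
  if (any(is.na(study))) rlang::abort("study label missing for some samples")
  out <- matrix(NA_real_, length(genes), length(ids),
                dimnames = list(genes, ids))
  excluded <- character()
  for (g in genes) {
    paired <- !is.na(p[g, ]) & !is.na(m[g, ])
    if (sum(paired) < cfg$min_paired_samples) {
      excluded <- c(excluded, g)
      next
    }
    oh <- cbind(intercept = 1, one_hot_studies(study[paired]))
    res_m <- ols_fit(m[g, paired], oh)$residuals
    res_p <- ols_fit(p[g, paired], oh)$residuals
    stage2 <- ols_fit(res_p, cbind(intercept = 1, mrna = res_m))
    out[g, paired] <- stage2$residuals
  }
  if (length(excluded) > 0) {
    rlang::inform(sprintf(
      "%d gene(s) below the paired-sample minimum excluded from residuals",
      length(excluded)))
    out <- out[setdiff(genes, excluded), , drop = FALSE]
  }
  if (nrow(out) == 0) rlang::abort("no genes passed the pairing minimum")
  r <- omics_matrix(out, "residual")
  attr(r, "excluded_genes") <- excluded
  r
}

#' Classify hit mechanisms across the three data layers
#'
#' Combines the protein, mRNA, and protein-residual screens (run on the
#' identical directed pair set) into a per-pair mechanism call, separately
#' for each effect sign: `transcriptional` when the mRNA screen is a hit
#' but the residual screen is not; `post_transcriptional` when the
#' residual screen is a hit but the mRNA screen is not; `both_layers` when
#' both are; `protein_only` when only the protein screen is; `none` when
#' no layer is a hit.
#'
#' @param protein_rows,mrna_rows,residual_rows `screen_result` tibbles over
#'   the same directed pair set.
#' @return A tibble: `lost_gene`, `responder_gene`, `class` (the effect
#'   sign the call refers to, or `"none"`), `mechanism`, and the per-layer
#'   hit flags.
#' @export
classify_mechanism <- function(protein_rows, mrna_rows, residual_rows) {
  keyify <- function(df, nm) {
    df |>
      dplyr::select("lost_gene", "responder_gene", "class") |>
      dplyr::rename(!!nm := "class")
  }
  k1 <- keyify(protein_rows, "protein_class")
  k2 <- keyify(mrna_rows, "mrna_class")
  k3 <- keyify(residual_rows, "residual_class")
  if (nrow(k1) != nrow(k2) || nrow(k1) != nrow(k3)) {
    rlang::abort("layer results cover different pair sets")
  }
  joined <- k1 |>
    dplyr::inner_join(k2, by = c("lost_gene", "responder_gene")) |>
    dplyr::inner_join(k3, by = c("lost_gene", "responder_gene"))
  if (nrow(joined) != nrow(k1)) {
    rlang::abort("layer results cover different pair sets")
  }
  per_sign <- purrr::map(c("compensation", "collateral_loss"), function(cl) {
    joined |>
      dplyr::mutate(
        p_hit = !is.na(.data$protein_class) & .data$protein_class == cl,
        m_hit = !is.na(.data$mrna_class) & .data$mrna_class == cl,
        r_hit = !is.na(.data$residual_class) & .data$residual_class == cl
      ) |>
      dplyr::filter(.data$p_hit | .data$m_hit | .data$r_hit) |>
      dplyr::mutate(
        class = cl,
        mechanism = dplyr::case_when(
          .data$m_hit & .data$r_hit ~ "both_layers",
          .data$m_hit ~ "transcriptional",
          .data$r_hit ~ "post_transcriptional",
          TRUE ~ "protein_only"
        )) |>
      dplyr::select("lost_gene", "responder_gene", "class", "mechanism",
                    protein_hit = "p_hit", mrna_hit = "m_hit",
                    residual_hit = "r_hit")
  }) |> purrr::list_rbind()
  no_hit <- joined |>
    dplyr::anti_join(per_sign, by = c("lost_gene", "responder_gene")) |>
    dplyr::mutate(class = "none", mechanism = "none",
                  protein_hit = FALSE, mrna_hit = FALSE,
                  residual_hit = FALSE) |>
    dplyr::select("lost_gene", "responder_gene", "class", "mechanism",
                  "protein_hit", "mrna_hit", "residual_hit")
  dplyr::bind_rows(per_sign, no_hit) |>
    dplyr::arrange(.data$lost_gene, .data$responder_gene)
}
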