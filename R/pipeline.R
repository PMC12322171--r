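#' Run the full cohort screen across data layers
#'
#' Convenience wrapper chaining the cohort stages: pair filtering, loss
#' annotation and validation on the protein layer, the loss-response
#' screen on each requested layer (building the protein-residual layer on
#' demand), and mechanism classification when all three layers are run.
#'
#' @param cohort A `matched_cohort`.
#' @param pairs Annotated pair table.
#' @param cfg A [screen_config()].
#' @param layers Character subset of `c("protein", "mrna", "residual")`.
#' @return A list: `pairs` (testable pairs), `ledger` (exclusion ledger),
#'   `annotations` (loss annotations), `screens` (named list of
#'   `screen_result`s), `residual_matrix` (when built), and
#'   `mechanisms` (when all three layers were screened).
#' @export
#' @examples
#' sim <- generate_cohort(generator_config(n_samples = 200, n_genes = 200,
#'                                         n_pairs = 40, seed = 1))
#' out <- paralog_screen(sim$cohort, sim$pairs,
#'                       screen_config(min_study_size = 1))
#' glance(out$screens$protein)
paralog_screen <- function(cohort, pairs, cfg = screen_config(),
                           layers = "protein") {
  layers <- match.arg(layers, c("protein", "mrna", "residual"),
                      several.ok = TRUE)
  fp <- filter_pairs(pairs, cohort, cfg)
  genes <- unique(c(fp$pairs$gene_a, fp$pairs$gene_b))
  ann <- annotate_losses(cohort, intersect(genes, rownames(cohort$cn)), cfg)
  res_mat <- NULL
  if ("residual" %in% layers) {
    if (is.null(cohort$mrna)) rlang::abort("residual layer needs mRNA data")
    keep <- intersect(genes, intersect(rownames(cohort$protein),
                                       rownames(cohort$mrna)))
    res_mat <- make_residuals(
      omics_matrix(unclass(cohort$protein)[keep, , drop = FALSE], "protein"),
      omics_matrix(unclass(cohort$mrna)[keep, , drop = FALSE], "mrna"),
      cohort$samples, cfg)
  }
  screens <- purrr::map(setNames(layers, layers), function(l) {
    run_screen(cohort, fp$pairs, l, cfg, loss_annotations = ann,
               residual_matrix = res_mat)
  })
  out <- list(pairs = fp$pairs, ledger = fp$ledger, annotations = ann,
              screens = screens, residual_matrix = res_mat)
  if (all(c("protein", "mrna", "residual") %in% layers)) {
    out$mechanisms <- classify_mechanism(screens$protein, screens$mrna,
                                         screens$residual)
  }
  out
}
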