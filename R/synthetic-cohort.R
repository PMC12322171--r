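#' Generate a matched tumour cohort with planted paralog effects
#'
#' Simulates the data structure the cohort screen consumes: a gene-level
#' copy-number call matrix, an mRNA matrix carrying study effects and a
#' dosage response, and a protein matrix that tracks mRNA plus independent
#' noise, with left-censored missingness. A subset of disjoint paralog
#' pairs carries planted directed coupling: in samples where the lost gene
#' is hemizygously deleted (call -1) the responder gains (compensation) or
#' loses (collateral loss) `effect_size_delta` log2 units, applied to the
#' mRNA (transcriptional), to the protein only (post-transcriptional), or
#' to both layers.
#'
#' Planted lost genes are guaranteed at least 20 hemizygously lost samples
#' by rejection sampling of their call rows; pairs are placed on distinct
#' chromosomes so the same-chromosome filter never removes truth pairs.
#'
#' @param cfg A [generator_config()].
#' @return A list with `cohort` (a `matched_cohort`), `pairs` (annotated
#'   pair table), and `truth` (tibble: `lost_gene`, `responder_gene`,
#'   `direction` up/down, `mechanism`, `delta`).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  n_g <- cfg$n_genes; n_s <- cfg$n_samples
  genes <- sprintf("G%04d", seq_len(n_g))
  sample_ids <- sprintf("S%04d", seq_len(n_s))
  study <- sprintf("study_%02d", rep(seq_len(cfg$n_studies), length.out = n_s))
  samples <- tibble::tibble(sample_id = sample_ids, study = sort(study))
  chrom <- as.character(rep(seq_len(22), length.out = n_g))

  # disjoint pairs: consecutive genes, always on different chromosomes
  pair_idx <- seq_len(cfg$n_pairs)
  ia <- 2 * pair_idx - 1; ib <- 2 * pair_idx
  pairs <- tibble::tibble(
    gene_a = genes[ia], gene_b = genes[ib],
    sequence_identity = stats::runif(cfg$n_pairs, 0.3, 0.95),
    family_size = sample(2:10, cfg$n_pairs, replace = TRUE),
    chromosome_a = chrom[ia], chromosome_b = chrom[ib]
  )

  n_comp <- round(cfg$frac_compensation * cfg$n_pairs)
  n_coll <- round(cfg$frac_collateral * cfg$n_pairs)
  planted <- sample(pair_idx, n_comp + n_coll)
  truth <- if (n_comp + n_coll > 0) {
    tibble::tibble(
      lost_gene = pairs$gene_b[planted],
      responder_gene = pairs$gene_a[planted],
      direction = rep(c("up", "down"), c(n_comp, n_coll)),
      mechanism = sample(names(cfg$mechanism_mix), n_comp + n_coll,
                         replace = TRUE, prob = cfg$mechanism_mix),
      delta = cfg$effect_size_delta
    )
  } else {
    tibble::tibble(lost_gene = character(), responder_gene = character(),
                   direction = character(), mechanism = character(),
                   delta = numeric())
  }

  # copy-number calls: -2 rare, -1 at a per-gene frequency, +1 occasional
  p_hemi <- stats::runif(n_g, cfg$loss_frequency_range[1],
                         cfg$loss_frequency_range[2])
  draw_calls <- function(ph) {
    sample(c(-2L, -1L, 0L, 1L), n_s, replace = TRUE,
           prob = c(0.01, ph, 1 - ph - 0.06, 0.05))
  }
  cn <- matrix(0L, n_g, n_s, dimnames = list(genes, sample_ids))
  for (g in seq_len(n_g)) cn[g, ] <- draw_calls(p_hemi[g])
  min_lost <- 20L
  for (g in match(truth$lost_gene, genes)) {
    tries <- 0L
    while (sum(cn[g, ] == -1L) < min_lost) {
      tries <- tries + 1L
      if (tries > 50L) {
        rlang::abort(paste0(
          "generator config cannot supply ", min_lost,
          " lost samples for planted gene ", genes[g]))
      }
      cn[g, ] <- draw_calls(max(p_hemi[g], min_lost * 1.5 / n_s))
    }
  }

  baseline <- stats::rnorm(n_g, mean = 6, sd = 1.5)
  # planted-pair genes get above-median baselines so left-censoring never
  # strips truth pairs of coverage or loss-sample quantification
  planted_genes <- match(c(truth$lost_gene, truth$responder_gene), genes)
  if (length(planted_genes) > 0) {
    baseline[planted_genes] <- 6 + abs(stats::rnorm(length(planted_genes),
                                                    0, 1.5))
  }
  study_eff <- matrix(stats::rnorm(n_g * cfg$n_studies, 0, cfg$sd_study),
                      n_g, cfg$n_studies)
  study_idx <- as.integer(factor(samples$study))
  mrna <- baseline + study_eff[, study_idx] +
    cfg$cn_mrna_slope * cn +
    matrix(stats::rnorm(n_g * n_s, 0, cfg$sd_mrna), n_g, n_s)
  dimnames(mrna) <- list(genes, sample_ids)

  # planted coupling keyed to the lost partner's hemizygous call
  pt_effect <- matrix(0, n_g, n_s, dimnames = list(genes, sample_ids))
  for (k in seq_len(nrow(truth))) {
    lost_row <- match(truth$lost_gene[k], genes)
    resp_row <- match(truth$responder_gene[k], genes)
    in_loss <- cn[lost_row, ] == -1L
    signed <- if (truth$direction[k] == "up") truth$delta[k] else -truth$delta[k]
    if (truth$mechanism[k] %in% c("transcriptional", "both")) {
      mrna[resp_row, in_loss] <- mrna[resp_row, in_loss] + signed
    }
    if (truth$mechanism[k] %in% c("post_transcriptional", "both")) {
      pt_effect[resp_row, in_loss] <- pt_effect[resp_row, in_loss] + signed
    }
  }

  protein <- mrna + pt_effect +
    matrix(stats::rnorm(n_g * n_s, 0, cfg$sd_protein), n_g, n_s)

  # left-censored missingness: the lowest-abundance cells go undetected
  if (cfg$missing_rate > 0) {
    cut <- stats::quantile(protein, cfg$missing_rate)
    protein[protein < cut] <- NA_real_
  }

  cohort <- align_cohort(
    protein = omics_matrix(protein, "protein"),
    mrna = omics_matrix(mrna, "mrna"),
    cn = copy_state_matrix(cn),
    samples = samples,
    cfg = screen_config(min_study_size = 1)
  )
  list(cohort = cohort, pairs = pairs, truth = truth)
}
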