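#' Screen configuration
#'
#' Bundles every threshold used by the isogenic and cohort screens. Defaults
#' reproduce the published analysis settings: hits require FDR < 5% *and*
#' uncorrected p < 0.05; genes must be hemizygously lost (copy-number call
#' -1) in at least 20 samples and quantified in at least 20 of them; studies
#' with fewer than 90 matched samples are dropped at alignment; paralog
#' pairs with sequence identity <= 0.2 or family size >= 20 are excluded,
#' as are pairs where either protein is observed in fewer than half the
#' samples; same-chromosome pairs are excluded in the cohort screen (the
#' isogenic screen keeps them).
#'
#' @param fdr_threshold FDR cut-off for hit calling (fraction, default 0.05).
#' @param p_threshold Uncorrected p-value cut-off (fraction, default 0.05).
#' @param min_lost_samples Minimum hemizygously lost samples for a gene to be
#'   eligible for loss-response testing (default 20).
#' @param min_study_size Minimum post-alignment study size; smaller studies
#'   are dropped (default 90).
#' @param coverage_fraction Minimum fraction of samples in which each pair
#'   member's protein must be observed (default 0.5).
#' @param identity_min_exclusive Pairs with sequence identity at or below
#'   this value are excluded (default 0.2).
#' @param family_size_max_exclusive Pairs with family size at or above this
#'   value are excluded (default 20).
#' @param exclude_same_chromosome Drop pairs whose members share a
#'   chromosome (default TRUE; the isogenic pipeline passes FALSE).
#' @param min_paired_samples Minimum paired observed protein/mRNA samples a
#'   gene needs to enter the residual layer (default 30).
#'
#' @return A list of class `screen_config`.
#' @export
#' @examples
#' cfg <- screen_config()
#' cfg$min_lost_samples
screen_config <- function(fdr_threshold = 0.05,
                          p_threshold = 0.05,
                          min_lost_samples = 20,
                          min_study_size = 90,
                          coverage_fraction = 0.5,
                          identity_min_exclusive = 0.2,
                          family_size_max_exclusive = 20,
                          exclude_same_chromosome = TRUE,
                          min_paired_samples = 30) {
  for (f in c(fdr_threshold, p_threshold, coverage_fraction,
              identity_min_exclusive)) {
    if (!is.numeric(f) || length(f) != 1 || f <= 0 || f >= 1) {
      rlang::abort("screen_config thresholds must be single numbers in (0, 1)")
    }
  }
  for (k in c(min_lost_samples, min_study_size, family_size_max_exclusive,
              min_paired_samples)) {
    if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
      rlang::abort("screen_config counts must be single integers >= 1")
    }
  }
  structure(
    list(
      fdr_threshold = fdr_threshold,
      p_threshold = p_threshold,
      min_lost_samples = as.integer(min_lost_samples),
      min_study_size = as.integer(min_study_size),
      coverage_fraction = coverage_fraction,
      identity_min_exclusive = identity_min_exclusive,
      family_size_max_exclusive = as.integer(family_size_max_exclusive),
      exclude_same_chromosome = isTRUE(exclude_same_chromosome),
      min_paired_samples = as.integer(min_paired_samples)
    ),
    class = "screen_config"
  )
}

#' Synthetic cohort generator configuration
#'
#' Parameters of the matched-cohort simulator. Defaults describe a mid-sized
#' pan-cancer-style cohort: 600 tumours across 6 studies, 2000 genes of
#' which 1000 form 500 disjoint paralog pairs, 10% of pairs carrying planted
#' compensation and 10% planted collateral loss at 0.5 log2 units, with a
#' copy-number dosage slope of 0.5 log2 units per call unit and left-censored
#' proteomic missingness at 5%.
#'
#' @param n_samples Number of tumour samples (default 600).
#' @param n_studies Number of studies / cancer types (default 6).
#' @param n_genes Number of genes (default 2000).
#' @param n_pairs Number of disjoint paralog pairs (default 500).
#' @param frac_compensation Fraction of pairs with planted compensation
#'   (default 0.10).
#' @param frac_collateral Fraction of pairs with planted collateral loss
#'   (default 0.10).
#' @param mechanism_mix Named fractions over mechanisms
#'   `c(transcriptional=, post_transcriptional=, both=)`; default equal
#'   thirds.
#' @param effect_size_delta Planted effect size in log2 units (default 0.5).
#' @param loss_frequency_range Interval for per-gene hemizygous-loss
#'   frequency (default `c(0.05, 0.25)`).
#' @param sd_study SD of per-gene study effects (default 0.3).
#' @param sd_mrna SD of mRNA noise (default 0.4).
#' @param sd_protein SD of protein noise on top of mRNA (default 0.4).
#' @param cn_mrna_slope Dosage effect on mRNA, log2 units per copy-number
#'   call unit (default 0.5).
#' @param missing_rate Fraction of lowest-abundance protein cells censored
#'   (default 0.05).
#' @param feature_bias Strength of label-feature association used by
#'   [generate_feature_tables()]; 0 gives null tables (default 1).
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 600,
                             n_studies = 6,
                             n_genes = 2000,
                             n_pairs = 500,
                             frac_compensation = 0.10,
                             frac_collateral = 0.10,
                             mechanism_mix = c(transcriptional = 1 / 3,
                                               post_transcriptional = 1 / 3,
                                               both = 1 / 3),
                             effect_size_delta = 0.5,
                             loss_frequency_range = c(0.05, 0.25),
                             sd_study = 0.3,
                             sd_mrna = 0.4,
                             sd_protein = 0.4,
                             cn_mrna_slope = 0.5,
                             missing_rate = 0.05,
                             feature_bias = 1,
                             seed = 1L) {
  stopifnot(
    frac_compensation >= 0, frac_collateral >= 0,
    frac_compensation + frac_collateral <= 1,
    sd_study > 0, sd_mrna > 0, sd_protein > 0,
    missing_rate >= 0, missing_rate < 1,
    length(loss_frequency_range) == 2,
    loss_frequency_range[1] > 0,
    loss_frequency_range[2] <= 1,
    n_pairs * 2 <= n_genes
  )
  mm <- mechanism_mix / sum(mechanism_mix)
  if (!setequal(names(mm),
                c("transcriptional", "post_transcriptional", "both"))) {
    rlang::abort(
      "mechanism_mix must name transcriptional, post_transcriptional, both")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_studies = as.integer(n_studies),
      n_genes = as.integer(n_genes),
      n_pairs = as.integer(n_pairs),
      frac_compensation = frac_compensation,
      frac_collateral = frac_collateral,
      mechanism_mix = mm,
      effect_size_delta = effect_size_delta,
      loss_frequency_range = loss_frequency_range,
      sd_study = sd_study,
      sd_mrna = sd_mrna,
      sd_protein = sd_protein,
      cn_mrna_slope = cn_mrna_slope,
      missing_rate = missing_rate,
      feature_bias = feature_bias,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}
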