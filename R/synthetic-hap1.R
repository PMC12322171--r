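#' Generate an isogenic knockout proteome experiment
#'
#' Simulates a label-free quantification experiment over a panel of
#' single-gene knockout clones plus a pool of wild-type replicates, on the
#' raw-intensity scale [preprocess_lfq()] expects. Each protein gets a
#' log-normal-style baseline; the targeted protein drops by `ko_drop` log2
#' units in its clone's replicates; planted paralog responses add a signed
#' log2 shift to a responder protein in one clone. The lowest-intensity
#' cells are left-censored to missing.
#'
#' @param n_clones Number of knockout clones, each targeting a distinct
#'   gene (default 10).
#' @param n_proteins Number of quantified proteins (default 800).
#' @param n_wt_reps Wild-type replicates (default 12).
#' @param n_ko_reps Replicates per knockout clone (default 4).
#' @param ko_drop Knockout effect on the targeted protein, log2 units
#'   (default 2).
#' @param planted_responses Tibble with columns `clone_id`,
#'   `responder_gene`, `delta` (signed log2 shift), or `NULL` for none.
#' @param sd_noise Replicate noise SD, log2 units (default 0.3).
#' @param missing_rate Fraction of lowest cells censored (default 0.05).
#' @param seed Integer seed.
#' @return A list with `matrix` (raw intensities, proteins x samples),
#'   `design` (tibble: `clone_id`, `target_gene`, list-columns
#'   `ko_samples`, `wt_samples`), and `truth` (the planted responses).
#' @export
generate_hap1 <- function(n_clones = 10, n_proteins = 800,
                          n_wt_reps = 12, n_ko_reps = 4,
                          ko_drop = 2.0, planted_responses = NULL,
                          sd_noise = 0.3, missing_rate = 0.05,
                          seed = 1L) {
  stopifnot(n_wt_reps >= 2, n_ko_reps >= 2, n_clones >= 1,
            n_proteins >= n_clones)
  set.seed(seed)
  genes <- sprintf("P%04d", seq_len(n_proteins))
  targets <- genes[seq_len(n_clones)]
  clones <- sprintf("KO_%s", targets)
  wt_samples <- sprintf("WT_r%02d", seq_len(n_wt_reps))
  ko_samples <- as.vector(t(outer(clones, seq_len(n_ko_reps),
                                  function(cl, r) sprintf("%s_r%d", cl, r))))
  all_samples <- c(wt_samples, ko_samples)

  if (!is.null(planted_responses) && nrow(planted_responses) > 0) {
    need <- c("clone_id", "responder_gene", "delta")
    if (!all(need %in% names(planted_responses))) {
      rlang::abort("planted_responses needs clone_id, responder_gene, delta")
    }
    if (length(setdiff(planted_responses$responder_gene, genes)) > 0 ||
        !all(planted_responses$clone_id %in% clones)) {
      rlang::abort("planted response references an unmodelled gene or clone")
    }
  }

  baseline <- stats::rnorm(n_proteins, mean = 25, sd = 2)
  # targets and planted responders get above-median baselines so
  # left-censoring cannot silence the proteins the experiment is about
  protected <- match(unique(c(targets,
                              planted_responses$responder_gene)), genes)
  baseline[protected] <- 25 + abs(stats::rnorm(length(protected), 0, 2))
  log2m <- matrix(baseline, n_proteins, length(all_samples),
                  dimnames = list(genes, all_samples))
  log2m <- log2m + matrix(stats::rnorm(length(log2m), 0, sd_noise),
                          nrow = n_proteins)

  clone_cols <- function(cl) grep(paste0("^", cl, "_r"), all_samples)
  for (i in seq_len(n_clones)) {
    log2m[targets[i], clone_cols(clones[i])] <-
      log2m[targets[i], clone_cols(clones[i])] - ko_drop
  }
  if (!is.null(planted_responses) && nrow(planted_responses) > 0) {
    for (k in seq_len(nrow(planted_responses))) {
      g <- planted_responses$responder_gene[k]
      cols <- clone_cols(planted_responses$clone_id[k])
      log2m[g, cols] <- log2m[g, cols] + planted_responses$delta[k]
    }
  }

  raw <- 2^log2m
  if (missing_rate > 0) {
    cut <- stats::quantile(raw, missing_rate)
    raw[raw < cut] <- NA_real_
  }

  design <- tibble::tibble(
    clone_id = clones,
    target_gene = targets,
    ko_samples = purrr::map(clones, ~ all_samples[clone_cols(.x)]),
    wt_samples = list(wt_samples)
  )
  truth <- planted_responses %||%
    tibble::tibble(clone_id = character(), responder_gene = character(),
                   delta = numeric())
  list(matrix = omics_matrix(raw, "protein"), design = design, truth = truth)
}
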