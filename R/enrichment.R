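battery_classes <- c("compensation", "collateral_loss")

#' Binary-feature enrichment battery
#'
#' For every binary (logical) feature and each hit class, tests whether
#' the feature is enriched among hits relative to non-hit pairs with an
#' exact 2x2 test, on the complete cases of that feature.
#' Benjamini-Hochberg adjustment pools the whole battery.
#'
#' @param features Feature table from [assemble_features()] (element
#'   `features`), with a `pair_class` label column.
#' @param binary_features Names of the flag columns to test; defaults to
#'   all logical columns.
#' @return An enrichment tibble: `feature`, `comparison`, the 2x2 counts,
#'   `odds_ratio`, `p`, `fdr`, `n_used`, `testable`.
#' @export
binary_battery <- function(features,
                           binary_features = names(features)[
                             purrr::map_lgl(features, is.logical)]) {
  rows <- purrr::map(battery_classes, function(cl) {
    sub <- features |> dplyr::filter(.data$pair_class %in% c(cl, "none"))
    purrr::map(binary_features, function(f) {
      v <- sub[[f]]
      ok <- !is.na(v)
      hit <- sub$pair_class[ok] == cl
      v <- v[ok]
      a <- sum(hit & v); b <- sum(hit & !v)
      c_ <- sum(!hit & v); d <- sum(!hit & !v)
      testable <- (a + b) > 0 && (c_ + d) > 0 && (a + c_) > 0 && (b + d) > 0
      res <- if (testable) exact_2x2(a, b, c_, d) else
        list(odds_ratio = NA_real_, p_value = NA_real_)
      tibble::tibble(feature = f, comparison = paste0(cl, "_vs_non_hit"),
                     a = a, b = b, c = c_, d = d,
                     odds_ratio = res$odds_ratio, p = res$p_value,
                     n_used = a + b + c_ + d, testable = testable)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows$fdr <- NA_real_
  rows$fdr[rows$testable] <- bh_adjust(rows$p[rows$testable])
  rows
}

#' Quantitative-feature group-comparison battery
#'
#' For every continuous feature and each hit class, compares hits against
#' non-hit pairs with a two-tailed pooled-variance t-test and Cohen's d,
#' on the complete cases of that feature. Benjamini-Hochberg adjustment
#' pools the battery.
#'
#' @param features Feature table with a `pair_class` column.
#' @param quantitative_features Names of the continuous columns; defaults
#'   to all numeric columns except identifiers.
#' @return An effect-size tibble: `feature`, `comparison`, `cohen_d`, `t`,
#'   `df`, `p`, `fdr`, `n_hit`, `n_non_hit`, `testable`.
#' @export
quantitative_battery <- function(features,
                                 quantitative_features =
                                   names(features)[
                                     purrr::map_lgl(features, is.numeric)]) {
  rows <- purrr::map(battery_classes, function(cl) {
    sub <- features |> dplyr::filter(.data$pair_class %in% c(cl, "none"))
    purrr::map(quantitative_features, function(f) {
      x <- sub[[f]][sub$pair_class == cl]
      y <- sub[[f]][sub$pair_class == "none"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      out <- tibble::tibble(feature = f,
                            comparison = paste0(cl, "_vs_non_hit"),
                            cohen_d = NA_real_, t = NA_real_,
                            df = NA_real_, p = NA_real_,
                            n_hit = length(x), n_non_hit = length(y),
                            testable = FALSE)
      if (length(x) >= 2 && length(y) >= 2) {
        tt <- tryCatch(pooled_t(x, y), error = function(e) NULL)
        if (!is.null(tt)) {
          out$cohen_d <- tt$cohen_d; out$t <- tt$t; out$df <- tt$df
          out$p <- tt$p_value; out$testable <- TRUE
        }
      }
      out
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows$fdr <- NA_real_
  rows$fdr[rows$testable] <- bh_adjust(rows$p[rows$testable])
  rows
}

#' Ubiquitination-site battery across mechanism groups
#'
#' Compares responder ubiquitination-site counts between mechanism-defined
#' groups — post-transcriptionally regulated hits (residual-layer hits),
#' exclusively transcriptional hits (mRNA hits that are not residual
#' hits), and never-hit pairs — with complex-membership controls: members
#' of any catalogued complex, members of large complexes (more than 10
#' subunits), and genes never in a complex. All groups are restricted to
#' tested responders. Contrasts use the two-sided rank-sum test with
#' Cliff's delta.
#'
#' @param mechanism_calls Output of [classify_mechanism()].
#' @param ubiq Tibble `gene`, `ubiq_sites` (absent genes count 0).
#' @param complexes Complex catalog tibble.
#' @param class Hit class to stratify on (default `"compensation"`).
#' @return A tibble: `group_a`, `group_b`, `n_a`, `n_b`, `cliffs_delta`,
#'   `U`, `p`.
#' @export
ubiq_battery <- function(mechanism_calls, ubiq, complexes,
                         class = "compensation") {
  mc <- mechanism_calls
  tested_resp <- unique(mc$responder_gene)
  counts <- setNames(ubiq_count(tested_resp, ubiq), tested_resp)
  complex_members <- unique(unlist(complexes$members))
  sizes <- purrr::map_int(complexes$members, length)
  large_members <- unique(unlist(complexes$members[sizes > 10]))
  groups <- list(
    post_transcriptional = unique(
      mc$responder_gene[mc$class == class & mc$residual_hit]),
    transcriptional_only = unique(
      mc$responder_gene[mc$class == class & mc$mrna_hit & !mc$residual_hit]),
    non_hit = unique(mc$responder_gene[mc$class == "none"]),
    complex_member = intersect(tested_resp, complex_members),
    large_complex_member = intersect(tested_resp, large_members),
    non_complex_member = setdiff(tested_resp, complex_members)
  )
  contrasts <- list(
    c("post_transcriptional", "transcriptional_only"),
    c("post_transcriptional", "non_hit"),
    c("transcriptional_only", "non_hit"),
    c("post_transcriptional", "complex_member"),
    c("large_complex_member", "non_complex_member")
  )
  purrr::map(contrasts, function(ct) {
    x <- counts[groups[[ct[1]]]]; y <- counts[groups[[ct[2]]]]
    if (length(x) == 0 || length(y) == 0) {
      rlang::warn(sprintf("empty group in contrast %s vs %s; skipped",
                          ct[1], ct[2]))
      return(NULL)
    }
    rs <- ranksum_cliffs(x, y)
    tibble::tibble(group_a = ct[1], group_b = ct[2],
                   n_a = length(x), n_b = length(y),
                   cliffs_delta = rs$cliffs_delta, U = rs$U, p = rs$p_value)
  }) |> purrr::list_rbind()
}

#' Overlap with an external regulatory-direction table
#'
#' Compares this pipeline's hit sets against an external table of directed
#' perturbation responses (e.g. a single-cell perturbation screen).
#' Perturbations are first filtered to construct-effective ones (adjusted
#' p below `target_fdr` on the perturbed gene's own target); external
#' pairs are then classed as upregulation or downregulation. For each
#' named hit set and each direction, an exact 2x2 test compares membership
#' in the hit set against the external direction, with the opposite
#' direction excluded from the negative group.
#'
#' @param hit_sets Named list of directed hit tibbles, each with
#'   `lost_gene`, `responder_gene`.
#' @param external Tibble: `perturbed_gene`, `responder_gene`,
#'   `adjusted_p`, `direction` (`"up"`/`"down"`/`"none"`),
#'   `target_adjusted_p`.
#' @param target_fdr Construct-effectiveness threshold (default 0.1).
#' @return An enrichment tibble: `hit_set`, `direction`, counts,
#'   `odds_ratio`, `p`.
#' @export
external_direction_overlap <- function(hit_sets, external,
                                       target_fdr = 0.1) {
  if (nrow(external) == 0) {
    rlang::warn("empty external table; no overlap tests run")
    return(tibble::tibble(hit_set = character(), direction = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), odds_ratio = numeric(),
                          p = numeric()))
  }
  ext <- external |>
    dplyr::filter(.data$target_adjusted_p < target_fdr) |>
    dplyr::mutate(key = paste(.data$perturbed_gene, .data$responder_gene,
                              sep = "|"))
  purrr::imap(hit_sets, function(hits, nm) {
    hit_keys <- paste(hits$lost_gene, hits$responder_gene, sep = "|")
    purrr::map(c("up", "down"), function(dir) {
      other <- setdiff(c("up", "down"), dir)
      sub <- ext |> dplyr::filter(.data$direction != other)
      pos <- sub$direction == dir
      inhit <- sub$key %in% hit_keys
      a <- sum(inhit & pos); b <- sum(inhit & !pos)
      c_ <- sum(!inhit & pos); d <- sum(!inhit & !pos)
      ft <- exact_2x2(a, b, c_, d)
      tibble::tibble(hit_set = nm, direction = dir, a = a, b = b, c = c_,
                     d = d, odds_ratio = ft$odds_ratio, p = ft$p_value)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
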