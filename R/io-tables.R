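#' Read a paralog pair table
#'
#' Mandatory columns: `gene_a`, `gene_b`, `sequence_identity`, `family_size`,
#' `chromosome_a`, `chromosome_b`. Each row is an unordered annotated pair;
#' the cohort screen derives directed tests from it.
#'
#' @param path TSV path.
#' @return A tibble with the mandatory columns (extras preserved).
#' @export
read_pair_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  validate_pair_table(df)
}

validate_pair_table <- function(df) {
  need <- c("gene_a", "gene_b", "sequence_identity", "family_size",
            "chromosome_a", "chromosome_b")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("pair table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read an undirected gene-gene edge list
#'
#' Mandatory columns `gene_a`, `gene_b`; an optional logical
#' `direct_physical` column marks direct physical evidence. Self-loops are
#' dropped and duplicate edges (in either orientation) collapsed, keeping
#' `direct_physical = TRUE` if any duplicate carried it.
#'
#' @param path TSV path.
#' @return A tibble of unique undirected edges with `gene_a < gene_b`.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  miss <- setdiff(c("gene_a", "gene_b"), names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("edge list missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  if (!"direct_physical" %in% names(df)) df$direct_physical <- FALSE
  df |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(direct_physical = any(.data$direct_physical),
                     .groups = "drop") |>
    dplyr::rename(gene_a = "lo", gene_b = "hi")
}

#' Read a protein-complex catalog
#'
#' Mandatory columns: `complex_id`, `members` (';'-separated gene symbols);
#' optional `source`.
#'
#' @param path TSV path.
#' @return A tibble with one row per complex and a `members` list-column of
#'   unique gene symbols.
#' @export
read_complex_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  miss <- setdiff(c("complex_id", "members"), names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("complex catalog missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  df |>
    dplyr::mutate(members = purrr::map(
      strsplit(.data$members, ";", fixed = TRUE),
      ~ unique(trimws(.x))
    )) |>
    tibble::as_tibble()
}

#' Read a per-gene feature table
#'
#' Mandatory column: `gene`; all other columns are numeric or flag features
#' (conservation, length, half-life, interface fraction, ubiquitination
#' counts, ...). Duplicate genes are rejected.
#'
#' @param path TSV path.
#' @return A tibble keyed by `gene`.
#' @export
read_gene_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (!"gene" %in% names(df)) rlang::abort("gene table missing 'gene' column")
  if (anyDuplicated(df$gene)) rlang::abort("duplicate genes in gene table")
  tibble::as_tibble(df)
}

#' Align cohort layers onto one sample universe
#'
#' Intersects the sample sets of the protein, (optional) mRNA, and
#' copy-number layers with the sample table, then drops studies whose
#' post-intersection size falls below `cfg$min_study_size`. The returned
#' cohort carries a provenance record of per-layer input counts, the
#' intersection size, and any dropped studies.
#'
#' @param protein An `omics_matrix` (protein layer).
#' @param mrna Optional `omics_matrix` (mRNA layer) or `NULL`.
#' @param cn A `copy_state_matrix`.
#' @param samples Sample table (`sample_id`, `study`).
#' @param cfg A [screen_config()].
#' @return A `matched_cohort` list with elements `protein`, `mrna`, `cn`,
#'   `samples`, `provenance`.
#' @export
align_cohort <- function(protein, mrna = NULL, cn, samples,
                         cfg = screen_config()) {
  samples <- validate_sample_table(samples)
  sets <- list(protein = colnames(protein), cn = colnames(cn),
               table = samples$sample_id)
  if (!is.null(mrna)) sets$mrna <- colnames(mrna)
  universe <- Reduce(intersect, sets)
  if (length(universe) == 0) {
    rlang::abort("no samples shared across cohort layers")
  }
  st <- samples |> dplyr::filter(.data$sample_id %in% universe)
  sizes <- st |> dplyr::count(.data$study, name = "n_samples")
  kept_studies <- sizes$study[sizes$n_samples >= cfg$min_study_size]
  dropped <- setdiff(sizes$study, kept_studies)
  st <- st |> dplyr::filter(.data$study %in% kept_studies)
  if (nrow(st) == 0) {
    rlang::abort("all studies fall below min_study_size after alignment")
  }
  ids <- st$sample_id
  prov <- tibble::tibble(
    step = c(paste0("input_", names(sets)), "intersection",
             if (length(dropped) > 0)
               paste0("dropped_study_", dropped) else character(),
             "retained"),
    count = c(vapply(sets, length, 1L), length(universe),
              if (length(dropped) > 0)
                sizes$n_samples[match(dropped, sizes$study)] else integer(),
              length(ids))
  )
  structure(
    list(
      protein = omics_matrix(unclass(protein)[, ids, drop = FALSE], "protein"),
      mrna = if (is.null(mrna)) NULL else
        omics_matrix(unclass(mrna)[, ids, drop = FALSE], "mrna"),
      cn = copy_state_matrix(
        matrix(unclass(cn)[, ids], nrow = nrow(cn),
               dimnames = list(rownames(cn), ids))),
      samples = st,
      provenance = prov
    ),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "<matched_cohort> %d samples, %d studies; protein %d genes%s, cn %d genes\n",
    nrow(x$samples), dplyr::n_distinct(x$samples$study), nrow(x$protein),
    if (is.null(x$mrna)) "" else sprintf(", mrna %d genes", nrow(x$mrna)),
    nrow(x$cn)))
  invisible(x)
}
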