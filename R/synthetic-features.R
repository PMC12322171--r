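#' Generate annotation tables correlated with planted labels
#'
#' Builds the annotation inputs of the feature/enrichment/modeling stages —
#' an interaction edge list, a complex catalog, an essentiality matrix, a
#' per-gene feature table and pair-level extras (TF co-regulation and
#' synthetic-lethality flags) — over the genes of a simulated pair table.
#' `cfg$feature_bias` controls how strongly features track the planted
#' compensation labels: at 0 every feature is independent of the labels
#' (null tables); at the default 1 compensation pairs receive stochastically
#' higher degree, shared-neighbour fraction, more-essential neighbours,
#' more frequent complex co-membership, higher responder ubiquitination and
#' conservation, and a higher synthetic-lethality rate.
#'
#' @param pairs Pair table from [generate_cohort()].
#' @param truth Truth table from [generate_cohort()].
#' @param cfg A [generator_config()]; uses `feature_bias` and `seed`.
#' @param n_cell_lines Number of simulated cell lines for the essentiality
#'   matrix (default 20).
#' @return A list: `edges` (undirected edge tibble), `complexes` (catalog
#'   tibble with `members` list-column), `essentiality` (genes x cell-lines
#'   matrix, lower = more essential), `gene_features` (tibble), and
#'   `pair_extras` (tibble: `gene_a`, `gene_b`, `coregulated_flag`,
#'   `synthetic_lethal_flag`).
#' @export
generate_feature_tables <- function(pairs, truth, cfg = generator_config(),
                                    n_cell_lines = 20) {
  set.seed(cfg$seed + 7919L)
  bias <- cfg$feature_bias
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  n <- length(genes)
  comp <- truth |> dplyr::filter(.data$direction == "up")
  comp_lost <- comp$lost_gene
  comp_resp <- comp$responder_gene
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  comp_keys <- key(comp$lost_gene, comp$responder_gene)
  is_comp_pair <- key(pairs$gene_a, pairs$gene_b) %in% comp_keys

  # base random graph plus label-driven extra edges and shared neighbours
  p0 <- min(1, 6 / n)
  base <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(base)) < p0
  edges <- tibble::tibble(gene_a = genes[base[keep, 1]],
                          gene_b = genes[base[keep, 2]],
                          direct_physical = stats::runif(sum(keep)) < 0.3)
  extra <- purrr::map(comp_lost, function(g) {
    k <- stats::rpois(1, 6 * bias)
    if (k == 0) return(NULL)
    tibble::tibble(gene_a = g, gene_b = sample(setdiff(genes, g), min(k, n - 1)),
                   direct_physical = FALSE)
  }) |> purrr::list_rbind()
  shared <- purrr::map2(comp$lost_gene, comp$responder_gene, function(a, b) {
    k <- stats::rpois(1, 2 * bias)
    if (k == 0) return(NULL)
    nb <- sample(setdiff(genes, c(a, b)), min(k, n - 2))
    tibble::tibble(gene_a = c(rep(a, length(nb)), rep(b, length(nb))),
                   gene_b = c(nb, nb), direct_physical = FALSE)
  }) |> purrr::list_rbind()
  direct_p <- 0.1 + pmin(0.4 * bias, 0.6) * is_comp_pair
  direct <- tibble::tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                           direct_physical = TRUE)[
    stats::runif(nrow(pairs)) < direct_p, ]
  edges <- dplyr::bind_rows(edges, extra, shared, direct) |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::mutate(lo = pmin(.data$gene_a, .data$gene_b),
                  hi = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(direct_physical = any(.data$direct_physical),
                     .groups = "drop") |>
    dplyr::rename(gene_a = "lo", gene_b = "hi")

  # essentiality: per-gene mean, neighbours of compensation-lost genes
  # shifted towards essentiality (more negative)
  gmean <- stats::rnorm(n, -0.2, 0.25)
  names(gmean) <- genes
  if (bias > 0 && length(comp_lost) > 0) {
    nb <- unique(c(edges$gene_b[edges$gene_a %in% comp_lost],
                   edges$gene_a[edges$gene_b %in% comp_lost]))
    gmean[nb] <- gmean[nb] - 0.3 * bias
  }
  ess <- matrix(stats::rnorm(n * n_cell_lines, rep(gmean, n_cell_lines), 0.15),
                n, n_cell_lines,
                dimnames = list(genes, sprintf("CL%02d", seq_len(n_cell_lines))))

  # complex catalog; compensation pairs co-inserted at a bias-driven rate
  n_cx <- 60
  complexes <- tibble::tibble(
    complex_id = sprintf("CPX%03d", seq_len(n_cx)),
    members = purrr::map(seq_len(n_cx),
                         ~ sample(genes, sample(3:12, 1))),
    source = "synthetic"
  )
  if (bias > 0) {
    co <- which(is_comp_pair & stats::runif(nrow(pairs)) < min(0.4 * bias, 0.8))
    for (i in co) {
      j <- sample(n_cx, 1)
      complexes$members[[j]] <- unique(c(complexes$members[[j]],
                                         pairs$gene_a[i], pairs$gene_b[i]))
    }
  }

  resp_shift <- as.integer(genes %in% comp_resp)
  gene_features <- tibble::tibble(
    gene = genes,
    conservation = stats::rpois(n, 250) + resp_shift * round(40 * bias),
    length = round(stats::rlnorm(n, log(500), 0.5)),
    half_life = ifelse(stats::runif(n) < 0.6, NA_real_,
                       stats::rlnorm(n, log(20), 0.6)),
    interface_fraction = ifelse(stats::runif(n) < 0.5, NA_real_,
                                stats::rbeta(n, 2, 6)),
    ubiq_sites = stats::rpois(n, 8) + resp_shift * stats::rpois(n, 4 * bias)
  )

  pair_extras <- tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    coregulated_flag = stats::runif(nrow(pairs)) <
      stats::plogis(stats::qlogis(0.2) + 0.8 * bias * is_comp_pair),
    synthetic_lethal_flag = stats::runif(nrow(pairs)) <
      stats::plogis(stats::qlogis(0.08) + 1.2 * bias * is_comp_pair)
  )

  list(edges = edges, complexes = complexes, essentiality = ess,
       gene_features = gene_features, pair_extras = pair_extras)
}
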