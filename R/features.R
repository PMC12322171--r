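#' Build a gene interaction network
#'
#' Undirected simple graph from an edge list (see [read_edge_list()]);
#' duplicate edges and self-loops are removed, the `direct_physical` flag
#' is OR-combined across duplicates.
#'
#' @param edges Edge tibble with `gene_a`, `gene_b`, optional
#'   `direct_physical`.
#' @return An undirected simple `igraph` graph.
#' @export
gene_network <- function(edges) {
  if (!"direct_physical" %in% names(edges)) edges$direct_physical <- FALSE
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "direct_physical")], directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(direct_physical = "max"))
}

#' Degree centrality of a gene
#'
#' Interaction count normalized by network size (`n_nodes - 1`). Genes
#' absent from the network get a missing value.
#'
#' @param net An `igraph` graph from [gene_network()].
#' @param gene Gene symbol(s).
#' @return Numeric vector of centralities in `[0, 1]`.
#' @export
degree_centrality <- function(net, gene) {
  nodes <- igraph::V(net)$name
  out <- rep(NA_real_, length(gene))
  present <- gene %in% nodes
  if (any(present)) {
    out[present] <- igraph::degree(net, gene[present]) /
      (igraph::vcount(net) - 1)
  }
  out
}

neighbours_of <- function(net, gene) {
  if (!gene %in% igraph::V(net)$name) return(NULL)
  igraph::V(net)$name[igraph::neighbors(net, gene)]
}

#' Jaccard index of two genes' interactor sets
#'
#' Shared interactors over the union of interactors, with the two genes
#' themselves removed from both neighbour sets (their mutual interaction is
#' carried separately by the direct-interaction flag). Returns 0 when the
#' union is empty, `NA` when either gene is absent from the network.
#'
#' @param net An `igraph` graph.
#' @param g1,g2 Gene symbols.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
jaccard_index <- function(net, g1, g2) {
  n1 <- neighbours_of(net, g1); n2 <- neighbours_of(net, g2)
  if (is.null(n1) || is.null(n2)) return(NA_real_)
  n1 <- setdiff(n1, c(g1, g2)); n2 <- setdiff(n2, c(g1, g2))
  u <- union(n1, n2)
  if (length(u) == 0) return(0)
  length(intersect(n1, n2)) / length(u)
}

#' Summarized essentiality of a gene's neighbours
#'
#' Per-gene essentiality scores are first aggregated across cell lines by
#' mean; the summary (median by default, mean available) is then taken
#' over the gene's network neighbours. Missing when the gene is absent or
#' has no scored neighbour.
#'
#' @param net An `igraph` graph.
#' @param gene Gene symbol.
#' @param ess Essentiality matrix, genes x cell lines (lower = more
#'   essential).
#' @param summary `"median"` (default) or `"mean"`.
#' @return A single score, or `NA`.
#' @export
neighbour_essentiality <- function(net, gene, ess,
                                   summary = c("median", "mean")) {
  summary <- match.arg(summary)
  nb <- neighbours_of(net, gene)
  if (is.null(nb)) return(NA_real_)
  per_gene <- rowMeans(ess, na.rm = TRUE)
  scores <- per_gene[intersect(nb, rownames(ess))]
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(NA_real_)
  if (summary == "median") stats::median(scores) else mean(scores)
}

#' Broadly essential genes and essential complexes
#'
#' A gene is broadly essential when its score falls below `threshold` in
#' at least `fraction` of cell lines; a complex is essential when it
#' contains at least one broadly essential member.
#'
#' @param catalog Complex catalog (see [read_complex_catalog()]).
#' @param ess Essentiality matrix, genes x cell lines.
#' @param threshold Score threshold (default -0.6).
#' @param fraction Minimum fraction of cell lines (default 0.8).
#' @return A list: `gene_flags` (tibble `gene`, `broadly_essential`),
#'   `complex_flags` (tibble `complex_id`, `essential`), and
#'   `essential_complex_members` (character vector of genes belonging to at
#'   least one essential complex).
#' @export
essential_complex_flags <- function(catalog, ess, threshold = -0.6,
                                    fraction = 0.8) {
  frac_below <- rowMeans(ess < threshold, na.rm = TRUE)
  gene_flags <- tibble::tibble(
    gene = rownames(ess),
    broadly_essential = frac_below >= fraction)
  be <- gene_flags$gene[gene_flags$broadly_essential]
  complex_flags <- catalog |>
    dplyr::mutate(essential = purrr::map_lgl(
      .data$members, ~ any(.x %in% be))) |>
    dplyr::select("complex_id", "essential")
  members <- unique(unlist(
    catalog$members[complex_flags$essential[
      match(catalog$complex_id, complex_flags$complex_id)]]))
  list(gene_flags = gene_flags, complex_flags = complex_flags,
       essential_complex_members = members %||% character())
}

#' Flag closest paralog pairs
#'
#' A pair is "closest" when each member's maximum-identity partner across
#' all pairs in the table is the other member; ties at the maximum
#' qualify.
#'
#' @param pairs Pair table with `gene_a`, `gene_b`, `sequence_identity`.
#' @return Logical vector, one flag per row of `pairs`.
#' @export
closest_pair_flags <- function(pairs) {
  long <- dplyr::bind_rows(
    tibble::tibble(gene = pairs$gene_a, id = pairs$sequence_identity),
    tibble::tibble(gene = pairs$gene_b, id = pairs$sequence_identity))
  best <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(best = max(.data$id), .groups = "drop")
  ba <- best$best[match(pairs$gene_a, best$gene)]
  bb <- best$best[match(pairs$gene_b, best$gene)]
  pairs$sequence_identity >= ba & pairs$sequence_identity >= bb
}

#' Ubiquitination-site count for a gene
#'
#' Proteins absent from the ubiquitination table count as having 0 sites.
#'
#' @param gene Gene symbol(s).
#' @param ubiq Tibble with columns `gene`, `ubiq_sites`.
#' @return Integer count(s), never negative, never missing.
#' @export
ubiq_count <- function(gene, ubiq) {
  v <- ubiq$ubiq_sites[match(gene, ubiq$gene)]
  v[is.na(v)] <- 0
  as.integer(v)
}

#' Interface fraction of a protein
#'
#' Interface residue count over protein length, clipped to `[0, 1]` with a
#' warning when inconsistent inputs push it above 1. Missing when the gene
#' has no model or no known length.
#'
#' @param gene Gene symbol(s).
#' @param interface Tibble with columns `gene`, `interface_residues`.
#' @param lengths Tibble with columns `gene`, `length`.
#' @return Fraction(s) in `[0, 1]` or `NA`.
#' @export
interface_fraction <- function(gene, interface, lengths) {
  res <- interface$interface_residues[match(gene, interface$gene)]
  len <- lengths$length[match(gene, lengths$gene)]
  out <- res / len
  if (any(out > 1, na.rm = TRUE)) {
    rlang::warn("interface fraction above 1 clipped; check inputs")
    out <- pmin(out, 1)
  }
  out
}

pair_families <- function(pairs) {
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  setNames(comp$membership, igraph::V(g)$name)
}

#' Flag pairs whose family touches a collateral-loss hit
#'
#' TRUE when any member of either gene's paralog family (connected
#' component of the full pair table) participates in at least one
#' collateral-loss hit, independently of the pair's own class.
#'
#' @param pairs Pair table (defines families).
#' @param screen_rows A `screen_result`.
#' @return Logical vector, one flag per row of `pairs`.
#' @export
family_crosshit_flag <- function(pairs, screen_rows) {
  fam <- pair_families(pairs)
  cl_hits <- screen_rows |>
    dplyr::filter(!is.na(.data$class), .data$class == "collateral_loss")
  hit_genes <- unique(c(cl_hits$lost_gene, cl_hits$responder_gene))
  hit_fams <- unique(fam[intersect(hit_genes, names(fam))])
  fam[pairs$gene_a] %in% hit_fams | fam[pairs$gene_b] %in% hit_fams
}

#' Assemble the per-pair feature table
#'
#' One row per unique unordered pair, combining screen labels with network,
#' essentiality, complex, and per-gene annotation features. The pair's
#' class is the hit class of its directed screen rows (compensation takes
#' precedence if both directions hit differently, which is rare); the
#' lost/responder orientation for asymmetric features comes from the
#' directed hit, or from the tested direction with the smaller p-value for
#' non-hits.
#'
#' @param pairs Testable pair table.
#' @param screen_rows `screen_result` for the labelling layer.
#' @param net `igraph` network from [gene_network()].
#' @param ess Essentiality matrix.
#' @param complexes Complex catalog tibble.
#' @param gene_features Per-gene feature tibble (`gene`, `conservation`,
#'   `length`, `half_life`, `interface_fraction`, `ubiq_sites`).
#' @param pair_extras Optional tibble (`gene_a`, `gene_b`,
#'   `coregulated_flag`, `synthetic_lethal_flag`).
#' @param neighbour_summary Passed to [neighbour_essentiality()].
#' @return A list: `features` (one tibble row per unique pair) and
#'   `missingness` (tibble: `feature`, `n_missing`, `fraction_missing`).
#' @export
assemble_features <- function(pairs, screen_rows, net, ess, complexes,
                              gene_features, pair_extras = NULL,
                              neighbour_summary = "median") {
  key <- paste(pmin(pairs$gene_a, pairs$gene_b),
               pmax(pairs$gene_a, pairs$gene_b))
  if (anyDuplicated(key)) rlang::abort("duplicate unordered pair in table")

  rows <- screen_rows |>
    dplyr::filter(.data$testable) |>
    dplyr::mutate(key = paste(pmin(.data$lost_gene, .data$responder_gene),
                              pmax(.data$lost_gene, .data$responder_gene)))
  orient <- rows |>
    dplyr::group_by(.data$key) |>
    dplyr::arrange(.data$class == "none", .data$class == "collateral_loss",
                   .data$p, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("key", "lost_gene", "responder_gene", pair_class = "class")

  ecf <- essential_complex_flags(complexes, ess)
  in_any_complex <- unique(unlist(complexes$members))
  same_complex <- function(a, b) {
    any(purrr::map_lgl(complexes$members, ~ a %in% .x && b %in% .x))
  }
  gf <- gene_features
  gfv <- function(g, col) gf[[col]][match(g, gf$gene)]

  df <- tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b, key = key,
    sequence_identity = pairs$sequence_identity,
    family_size = pairs$family_size,
    closest_flag = closest_pair_flags(pairs)
  ) |>
    dplyr::left_join(orient, by = "key")
  # untested pairs keep a canonical orientation and a "none" label
  noor <- is.na(df$pair_class)
  df$lost_gene[noor] <- df$gene_b[noor]
  df$responder_gene[noor] <- df$gene_a[noor]
  df$pair_class[noor] <- "none"

  edge_ids <- igraph::as_edgelist(net)
  direct <- igraph::E(net)$direct_physical == 1
  direct_keys <- paste(pmin(edge_ids[direct, 1], edge_ids[direct, 2]),
                       pmax(edge_ids[direct, 1], edge_ids[direct, 2]))

  df <- df |>
    dplyr::mutate(
      degree_centrality_lost = degree_centrality(net, .data$lost_gene),
      jaccard = purrr::map2_dbl(.data$gene_a, .data$gene_b,
                                ~ jaccard_index(net, .x, .y)),
      neighbour_essentiality_lost = purrr::map_dbl(
        .data$lost_gene,
        ~ neighbour_essentiality(net, .x, ess, neighbour_summary)),
      either_in_complex = .data$gene_a %in% in_any_complex |
        .data$gene_b %in% in_any_complex,
      both_same_complex = purrr::map2_lgl(.data$gene_a, .data$gene_b,
                                          same_complex),
      either_in_essential_complex =
        .data$gene_a %in% ecf$essential_complex_members |
        .data$gene_b %in% ecf$essential_complex_members,
      direct_interaction_flag = .data$key %in% direct_keys,
      conservation_lost = gfv(.data$lost_gene, "conservation"),
      conservation_responder = gfv(.data$responder_gene, "conservation"),
      length_lost = gfv(.data$lost_gene, "length"),
      length_responder = gfv(.data$responder_gene, "length"),
      half_life = gfv(.data$responder_gene, "half_life"),
      interface_fraction = gfv(.data$responder_gene, "interface_fraction"),
      ubiq_sites_responder = ubiq_count(
        .data$responder_gene,
        dplyr::select(gf, "gene", "ubiq_sites")),
      family_crosshit_flag = family_crosshit_flag(pairs, screen_rows)
    )
  if (!is.null(pair_extras)) {
    pe <- pair_extras |>
      dplyr::mutate(key = paste(pmin(.data$gene_a, .data$gene_b),
                                pmax(.data$gene_a, .data$gene_b))) |>
      dplyr::select(-"gene_a", -"gene_b")
    df <- df |> dplyr::left_join(pe, by = "key")
  }
  df <- df |> dplyr::select(-"key")

  feature_cols <- setdiff(names(df), c("gene_a", "gene_b", "lost_gene",
                                       "responder_gene", "pair_class"))
  missingness <- tibble::tibble(
    feature = feature_cols,
    n_missing = purrr::map_int(feature_cols, ~ sum(is.na(df[[.x]]))),
    fraction_missing = purrr::map_dbl(feature_cols,
                                      ~ mean(is.na(df[[.x]])))
  ) |> dplyr::arrange(dplyr::desc(.data$fraction_missing))
  list(features = df, missingness = missingness)
}
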