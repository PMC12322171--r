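toy_net <- function() {
  gene_network(tibble::tibble(
    gene_a = c("hub", "hub", "hub", "hub", "A", "A", "B"),
    gene_b = c("s1", "s2", "s3", "A", "B", "C", "C"),
    direct_physical = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)))
}

test_that("degree centrality normalizes by network size minus one", {
  star <- gene_network(tibble::tibble(gene_a = "c",
                                      gene_b = c("a", "b", "d", "e")))
  expect_equal(degree_centrality(star, "c"), 1)
  expect_equal(degree_centrality(star, "a"), 0.25)
  expect_true(is.na(degree_centrality(star, "ghost")))
  net <- toy_net()
  # brute-force neighbour count oracle on the 7-node toy graph
  for (g in c("hub", "A", "B", "C", "s1")) {
    el <- tibble::tibble(
      gene_a = c("hub", "hub", "hub", "hub", "A", "A", "B"),
      gene_b = c("s1", "s2", "s3", "A", "B", "C", "C"))
    deg <- sum(el$gene_a == g | el$gene_b == g)
    expect_equal(degree_centrality(net, g), deg / 6)
  }
  expect_true(all(degree_centrality(net, c("hub", "A", "s1")) >= 0 &
                    degree_centrality(net, c("hub", "A", "s1")) <= 1))
})

test_that("jaccard excludes the pair members and handles edge cases", {
  net <- toy_net()
  # N(A)\{A,B} = {hub, C}; N(B)\{A,B} = {C} -> 1/2
  expect_equal(jaccard_index(net, "A", "B"), 0.5)
  expect_equal(jaccard_index(net, "A", "B"), jaccard_index(net, "B", "A"))
  # identical neighbour sets
  two <- gene_network(tibble::tibble(gene_a = c("x", "y", "x", "y"),
                                     gene_b = c("B", "B", "C", "C")))
  expect_equal(jaccard_index(two, "x", "y"), 1)
  # disjoint neighbour sets
  dj <- gene_network(tibble::tibble(gene_a = c("x", "y"),
                                    gene_b = c("p", "q")))
  expect_equal(jaccard_index(dj, "x", "y"), 0)
  expect_true(is.na(jaccard_index(net, "A", "ghost")))
})

test_that("neighbour essentiality aggregates by mean then summarizes", {
  net <- gene_network(tibble::tibble(gene_a = "g",
                                     gene_b = c("n1", "n2", "n3")))
  ess <- matrix(c(-0.9, -0.9, -0.2, -0.2, 0.1, 0.1, 0, 0), 4, 2,
                byrow = TRUE,
                dimnames = list(c("n1", "n2", "n3", "g"),
                                c("cl1", "cl2")))
  expect_equal(neighbour_essentiality(net, "g", ess), -0.2)
  expect_equal(neighbour_essentiality(net, "g", ess, "mean"),
               mean(c(-0.9, -0.2, 0.1)))
  solo <- gene_network(tibble::tibble(gene_a = "a", gene_b = "b"))
  expect_true(is.na(neighbour_essentiality(solo, "a",
                                           ess[c("n1", "n2"), ])))
  uniform <- matrix(-1, 3, 2, dimnames = list(c("n1", "n2", "n3"),
                                              c("c1", "c2")))
  expect_equal(neighbour_essentiality(net, "g", uniform), -1)
})

test_that("broad essentiality uses the at-least-80%-of-lines rule", {
  # gene below -0.6 in exactly 80% of 10 cell lines qualifies
  ess <- rbind(
    edge80 = c(rep(-0.7, 8), rep(0, 2)),
    below = c(rep(-0.7, 7), rep(0, 3)),
    never = rep(0, 10))
  colnames(ess) <- sprintf("c%02d", 1:10)
  catalog <- tibble::tibble(
    complex_id = c("cx1", "cx2"),
    members = list(c("edge80", "other"), c("below", "never")))
  out <- essential_complex_flags(catalog, ess)
  expect_true(out$gene_flags$broadly_essential[
    out$gene_flags$gene == "edge80"])
  expect_false(out$gene_flags$broadly_essential[
    out$gene_flags$gene == "below"])
  expect_equal(out$complex_flags$essential, c(TRUE, FALSE))
  expect_setequal(out$essential_complex_members, c("edge80", "other"))
})

test_that("closest-pair flags follow mutual-best-identity with ties", {
  pairs <- tibble::tibble(
    gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
    sequence_identity = c(0.9, 0.5, 0.95))
  # A's best is B (.9), B's best is C (.95): A-B not closest; B-C closest
  flags <- closest_pair_flags(pairs)
  expect_equal(flags, c(FALSE, FALSE, TRUE))
  # two-gene family: always closest
  expect_true(closest_pair_flags(tibble::tibble(
    gene_a = "X", gene_b = "Y", sequence_identity = 0.4)))
  # tie at the maximum qualifies both pairs
  tie <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("B", "C"),
                        sequence_identity = c(0.8, 0.8))
  expect_equal(closest_pair_flags(tie), c(TRUE, TRUE))
})

test_that("ubiquitination counts default to zero and never go negative", {
  ubiq <- tibble::tibble(gene = c("p1", "p2"), ubiq_sites = c(12L, 3L))
  expect_equal(ubiq_count(c("p1", "absent", "p2"), ubiq), c(12L, 0L, 3L))
  expect_true(all(ubiq_count(c("a", "b"), ubiq) >= 0))
})

test_that("interface fraction divides residues by length and clips", {
  interface <- tibble::tibble(gene = c("g1", "g2"),
                              interface_residues = c(50, 300))
  lengths <- tibble::tibble(gene = c("g1", "g2"), length = c(200, 250))
  expect_equal(interface_fraction("g1", interface, lengths), 0.25)
  expect_warning(v <- interface_fraction("g2", interface, lengths),
                 "clipped")
  expect_equal(v, 1)
  expect_true(is.na(suppressWarnings(
    interface_fraction("nomodel", interface, lengths))))
})

test_that("family cross-hit flags propagate through paralog families", {
  pairs <- tibble::tibble(
    gene_a = c("A", "A", "X"), gene_b = c("B", "C", "Y"),
    sequence_identity = 0.5, family_size = 3,
    chromosome_a = "1", chromosome_b = "2")
  rows <- tibble::tibble(
    lost_gene = "C", responder_gene = "A", class = "collateral_loss",
    testable = TRUE)
  flags <- family_crosshit_flag(pairs, rows)
  # A-B: sibling C is in a collateral-loss hit -> TRUE (family {A,B,C})
  expect_equal(flags, c(TRUE, TRUE, FALSE))
  # no hits anywhere: all FALSE
  none <- rows; none$class <- "none"
  expect_equal(family_crosshit_flag(pairs, none), c(FALSE, FALSE, FALSE))
})

test_that("feature assembly yields one row per unique pair with report", {
  sim <- generate_cohort(generator_config(n_samples = 240, n_studies = 3,
                                          n_genes = 240, n_pairs = 50,
                                          effect_size_delta = 1.5,
                                          sd_protein = 0.2, seed = 19))
  cfg <- screen_config(min_study_size = 1)
  fp <- filter_pairs(sim$pairs, sim$cohort, cfg)
  scr <- suppressMessages(run_screen(sim$cohort, fp$pairs, "protein", cfg))
  ft <- generate_feature_tables(sim$pairs, sim$truth,
                                generator_config(seed = 19))
  net <- gene_network(ft$edges)
  out <- assemble_features(fp$pairs, scr, net, ft$essentiality,
                           ft$complexes, ft$gene_features, ft$pair_extras)
  expect_equal(nrow(out$features), nrow(fp$pairs))
  key <- paste(pmin(out$features$gene_a, out$features$gene_b),
               pmax(out$features$gene_a, out$features$gene_b))
  expect_equal(anyDuplicated(key), 0)
  # flags are total; high-missing features are flagged as such
  expect_false(any(is.na(out$features$either_in_complex)))
  expect_false(any(is.na(out$features$ubiq_sites_responder)))
  hm <- out$missingness$feature[out$missingness$fraction_missing > 0.4]
  expect_true("half_life" %in% hm)
  # duplicate unordered pair errors
  dup <- dplyr::bind_rows(fp$pairs, fp$pairs[1, ])
  expect_error(assemble_features(dup, scr, net, ft$essentiality,
                                 ft$complexes, ft$gene_features),
               "duplicate")
})
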