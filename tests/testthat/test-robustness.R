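test_that("high-connectivity thresholding follows the strict-quantile convention", {
  # 10 distinct weights: the interpolated 90th percentile leaves exactly one
  g <- fake_chain_graph(seq(0.1, 1, by = 0.1))
  hc <- high_connectivity_edges(g, 0.90)
  expect_identical(nrow(hc$edges), 1L)
  expect_equal(hc$edges$weight, 1)
  expect_equal(hc$threshold, unname(quantile(seq(0.1, 1, 0.1), 0.9)))

  # ties: nothing is strictly above a constant weight distribution
  g2 <- fake_chain_graph(rep(0.4, 8))
  expect_identical(nrow(high_connectivity_edges(g2, 0.90)$edges), 0L)

  # quantile 0: everything strictly above the minimum
  g3 <- fake_chain_graph(c(0.2, 0.5, 0.9, 0.2))
  expect_identical(nrow(high_connectivity_edges(g3, 0)$edges), 2L)

  # magnitude, not sign, defines connectivity
  g4 <- fake_chain_graph(c(-0.9, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.65, 0.7, 0.8))
  hc4 <- high_connectivity_edges(g4, 0.90)
  expect_equal(hc4$edges$weight, -0.9)

  # empty graph: empty set, undefined threshold
  g5 <- fake_chain_graph(numeric(0))
  hc5 <- high_connectivity_edges(g5, 0.90)
  expect_identical(nrow(hc5$edges), 0L)
  expect_true(is.na(hc5$threshold))
})

test_that("the robustness index is the percentage of flagged runs", {
  expect_equal(connectivity_robustness_index(fake_ensemble(rep(0, 10))), 0)
  expect_equal(connectivity_robustness_index(fake_ensemble(rep(2, 10))), 100)
  counts <- c(rep(1, 42), rep(0, 58))
  expect_equal(connectivity_robustness_index(fake_ensemble(counts)), 42)
})

test_that("layer comparison classifies against the cutoff", {
  mk <- function(dna_pct, rna_pct)
    compare_layers(fake_ensemble(c(rep(1, dna_pct), rep(0, 100 - dna_pct))),
                   fake_ensemble(c(rep(1, rna_pct), rep(0, 100 - rna_pct))),
                   cutoff = 30)
  expect_identical(mk(42, 44)$classification, "active_keystone")
  expect_identical(mk(11, 6)$classification, "not_keystone")
  expect_identical(mk(100, 0)$classification, "abundance_only")
  expect_identical(mk(0, 100)$classification, "activity_only")
  r <- mk(42, 44)
  expect_equal(r$index_dna, 42)
  expect_equal(r$index_rna, 44)

  other <- fake_ensemble(rep(1, 10), focal_id = "T2")
  expect_error(compare_layers(fake_ensemble(rep(1, 10)), other), "mismatch")
})

test_that("permutation ensembles guard preconditions and are seed-deterministic", {
  cfg <- synthetic_config(n_samples = 30, n_taxa = 20, metadata_mode = "general",
                          seed = 51)
  sim <- simulate_dataset(cfg)
  pool <- setdiff(taxon_ids(sim$dna), "MAG_001")

  expect_error(run_permutation_ensemble("MAG_001", pool[1:10], sim$dna, sim$meta,
                                        n_perm = 2, n_companions = 14),
               "pool too small")
  expect_error(run_permutation_ensemble("MAG_001", pool, sim$dna, sim$meta,
                                        n_perm = 0), "n_perm")

  e1 <- run_permutation_ensemble("MAG_001", pool, sim$dna, sim$meta,
                                 n_perm = 4, n_companions = 6, seed = 9)
  e2 <- run_permutation_ensemble("MAG_001", pool, sim$dna, sim$meta,
                                 n_perm = 4, n_companions = 6, seed = 9)
  expect_identical(ensemble_summary(e1), ensemble_summary(e2))
  expect_true(all(vapply(e1$runs, function(r) length(r$companions), 0L) == 6L))
  expect_false(any(vapply(e1$runs, function(r) "MAG_001" %in% r$companions, TRUE)))
})

test_that("the index is invariant to relabeling companions and monotone in the quantile", {
  cfg <- synthetic_config(n_samples = 30, n_taxa = 15, n_hubs = 1, hub_degree = 4,
                          metadata_mode = "general", seed = 52)
  sim <- simulate_dataset(cfg)
  focal <- "MAG_001"
  pool <- setdiff(taxon_ids(sim$dna), focal)

  e <- run_permutation_ensemble(focal, pool, sim$dna, sim$meta, n_perm = 5,
                                n_companions = 6, seed = 4)

  # relabel all companion taxa (same order, new names): same index
  ren <- sim$dna$values
  colnames(ren) <- ifelse(colnames(ren) == focal, focal,
                          paste0("X", colnames(ren)))
  m_ren <- abundance_matrix(ren, layer = "dna")
  e_ren <- run_permutation_ensemble(focal, setdiff(colnames(ren), focal),
                                    m_ren, sim$meta, n_perm = 5,
                                    n_companions = 6, seed = 4)
  expect_equal(connectivity_robustness_index(e_ren),
               connectivity_robustness_index(e))

  # raising the quantile never increases a run's focal edge count
  counts <- sapply(c(0.5, 0.7, 0.9), function(q) {
    eq <- run_permutation_ensemble(focal, pool, sim$dna, sim$meta, n_perm = 5,
                                   n_companions = 6, quantile = q, seed = 4)
    vapply(eq$runs, `[[`, 0L, "focal_high_edges")
  })
  expect_true(all(apply(counts, 1, function(z) all(diff(z) <= 0))))
})

test_that("under a fully null community the index matches the exchangeability oracle", {
  # diagonal precision, zero environmental effects: every taxon is
  # statistically identical, so the focal flag rate must match the average
  # share of taxa involved in flagged edges across the same fitted graphs
  cfg <- synthetic_config(n_samples = 60, n_taxa = 30, n_hubs = 0,
                          background_degree = 0, metadata_mode = "general",
                          seed = 53)
  net <- generate_planted_network(cfg)
  expect_identical(sum(net$adjacency_dna), 0L)
  meta <- generate_metadata(cfg)
  m <- simulate_counts(net, meta, "dna", cfg)
  focal <- "MAG_001"
  e <- run_permutation_ensemble(focal, setdiff(net$taxon_ids, focal), m, meta,
                                n_perm = 30, n_companions = 14, seed = 6,
                                keep_graphs = TRUE)
  idx <- connectivity_robustness_index(e) / 100
  p_runs <- vapply(e$runs, function(r) {
    hc <- high_connectivity_edges(r$graph, e$quantile)
    taxa <- c(focal, r$companions)
    flagged <- unique(c(hc$edges$u, hc$edges$v))
    length(intersect(flagged, taxa)) / length(taxa)
  }, numeric(1))
  expected <- mean(p_runs)
  sd3 <- 3 * sqrt(sum(p_runs * (1 - p_runs))) / length(p_runs)
  expect_lt(abs(idx - expected), max(sd3, 1e-9))
})
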