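test_that("planted networks honour the requested degree structure and are valid precisions", {
  cfg <- synthetic_config(n_taxa = 30, n_hubs = 1, hub_degree = 8, seed = 5)
  net <- generate_planted_network(cfg)
  deg <- colSums(net$adjacency_dna)
  hub <- match(net$hub_ids, net$taxon_ids)
  expect_equal(unname(deg[hub]), 8)
  expect_true(all(deg[-hub] <= cfg$background_degree + 0L))
  ev <- eigen(net$precision_dna, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(isSymmetric(net$precision_dna))

  # same seed, bit-identical network; different seed, different support
  net2 <- generate_planted_network(cfg)
  expect_identical(net$precision_dna, net2$precision_dna)
  net3 <- generate_planted_network(synthetic_config(n_taxa = 30, n_hubs = 1,
                                                    hub_degree = 8, seed = 6))
  expect_false(identical(net$adjacency_dna, net3$adjacency_dna))

  expect_error(generate_planted_network(
    synthetic_config(n_taxa = 6, n_hubs = 3, hub_degree = 5, seed = 1)),
    "infeasible")
})

test_that("fixture metadata reproduces the 16-sample stratified-lake margins", {
  meta <- generate_metadata(synthetic_config(seed = 1))
  expect_identical(nrow(meta), 16L)
  expect_identical(as.integer(table(meta$depth_m)[c("5", "10", "15", "23.5")]),
                   c(2L, 2L, 6L, 6L))
  expect_identical(as.integer(table(meta$month)[c("July", "August", "September", "October")]),
                   c(3L, 6L, 2L, 5L))
  expect_identical(as.integer(table(meta$oxygen)[c("oxic", "anoxic", "oxycline")]),
                   c(4L, 9L, 3L))
  expect_silent(validate_metadata(meta))
})

test_that("general-mode metadata has finite environmental profiles at any size", {
  meta <- generate_metadata(synthetic_config(n_samples = 4,
                                             metadata_mode = "general", seed = 2))
  expect_identical(nrow(meta), 4L)
  env <- as.matrix(meta[, intersect(c("depth", "wtemp", "do_sat", "do_raw",
                                      "sp_cond", "pH", "chlor_rfu", "phyco_rfu",
                                      "fdom_rfu", "turb_fnu", "sampling_time"),
                                    names(meta))])
  expect_true(all(is.finite(env)))
})

test_that("simulated counts follow the planted model", {
  cfg <- synthetic_config(n_samples = 40, n_taxa = 25, metadata_mode = "general",
                          activity_decoupling = 0, seed = 9)
  net <- generate_planted_network(cfg)
  meta <- generate_metadata(cfg)
  m <- simulate_counts(net, meta, "dna", cfg)
  expect_identical(dim(m$values), c(40L, 25L))
  expect_true(all(m$values >= 0))
  expect_identical(m$normalisation, "raw")

  # decoupling 0: both layers share the ground-truth support
  expect_identical(net$adjacency_dna, net$adjacency_rna)

  # decoupling > 0 re-wires but preserves degrees
  cfg2 <- synthetic_config(n_taxa = 40, activity_decoupling = 0.5, seed = 9)
  net2 <- generate_planted_network(cfg2)
  expect_false(identical(net2$adjacency_dna, net2$adjacency_rna))
  expect_identical(colSums(net2$adjacency_dna), colSums(net2$adjacency_rna))

  # determinism
  expect_identical(simulate_counts(net, meta, "dna", cfg)$values, m$values)
})

test_that("with zero environmental effects the composition is independent of predictors", {
  cfg <- synthetic_config(n_samples = 500, n_taxa = 20, n_hubs = 0,
                          metadata_mode = "general", seed = 4)
  net <- generate_planted_network(cfg)
  expect_true(all(net$env_effects == 0))
  meta <- generate_metadata(cfg)
  m <- simulate_counts(net, meta, "dna", cfg)
  score <- rowMeans(clr_transform(m, 1)$values[, 1:10])
  X <- env_matrix(meta)
  rs <- apply(X, 2, function(x) cor(score, x))
  expect_true(all(abs(rs) < 0.1))
})

test_that("synthetic taxonomy resolution declines with rank as configured", {
  tax0 <- generate_taxonomy(50, unknown_rates = c(domain = 0, phylum = 0,
                                                  class = 0, order = 0,
                                                  family = 0, genus = 0,
                                                  species = 0), seed = 1)
  expect_true(all(tax0$species != "UNKNOWN"))

  tax <- generate_taxonomy(431, seed = 1)
  n_sp <- sum(tax$species != "UNKNOWN")
  expect_lt(abs(n_sp - 431 * 0.1), 3 * sqrt(431 * 0.9 * 0.1))

  # monotone-unknown invariant on every record
  rk <- as.matrix(tax[, c("domain", "phylum", "class", "order", "family",
                          "genus", "species")])
  known <- rk != "UNKNOWN"
  expect_true(all(apply(known, 1, function(z) all(diff(as.integer(z)) <= 0))))

  expect_error(generate_taxonomy(10, unknown_rates = c(domain = 0.5, phylum = 0,
                                                       class = 0, order = 0,
                                                       family = 0, genus = 0,
                                                       species = 0)),
               "non-decreasing")
})

test_that("written synthetic datasets can be read back identically", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(synthetic_config(n_taxa = 12, n_hubs = 1, hub_degree = 4, seed = 8))
  write_synthetic_dataset(sim, dir)
  dna <- read_abundance_table(file.path(dir, "abundance_dna.tsv"),
                              "sample_major", "dna")
  expect_equal(dna$values * 1, sim$dna$values * 1)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta$sample_id, sim$meta$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_identical(sort(truth$hub_ids), sort(sim$network$hub_ids))
})
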