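# Textbook correlation formulas used as the independent oracle for the
# screening step.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

test_that("correlation screen keeps pairs strong under every method", {
  v <- rbind(c(10, 20, 30, 40),
             c(11, 19, 31, 39),
             c(40, 30, 20, 10),
             c(5, 40, 10, 45))
  m <- tss_normalise(toy_abund(v))
  res <- sample_correlation_screen(m, threshold = 0.8)

  # brute force over all 6 pairs with the textbook formulas
  p <- t(apply(m$values, 1, identity))
  expected <- NULL
  for (i in 1:3) for (j in (i + 1):4) {
    rp <- pearson_oracle(p[i, ], p[j, ])
    rs <- spearman_oracle(p[i, ], p[j, ])
    if (rp > 0.8 && rs > 0.8)
      expected <- rbind(expected, c(i, j, rp, rs))
  }
  expect_identical(nrow(res), nrow(expected))
  expect_identical(res$sample_a, paste0("S", expected[, 1]))
  expect_equal(res$r_pearson, expected[, 3], tolerance = 1e-12)
  expect_equal(res$r_spearman, expected[, 4], tolerance = 1e-12)

  # identical profiles: r = 1 under both, reported
  dup <- tss_normalise(toy_abund(rbind(c(1, 2, 3), c(1, 2, 3), c(9, 1, 1))))
  res2 <- sample_correlation_screen(dup, threshold = 0.8)
  expect_identical(res2$sample_a, "S1")
  expect_equal(res2$r_pearson, 1)

  # perfect anti-rank is excluded
  anti <- tss_normalise(toy_abund(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 1, 4))))
  res3 <- sample_correlation_screen(anti, threshold = 0.8)
  expect_false(any(res3$sample_a == "S1" & res3$sample_b == "S2"))
})

test_that("Bray-Curtis matches hand-computed cases and stays in [0, 1]", {
  m <- toy_abund(rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.2, 0.8), c(1, 0), c(0, 1)))
  d <- bray_curtis(m)
  expect_equal(d$values[1, 3], 0)          # identical rows
  expect_equal(d$values[4, 5], 1)          # disjoint supports
  expect_equal(d$values[1, 2], 0.3)        # (0.3 + 0.3) / 2
  expect_true(isSymmetric(d$values))
  expect_identical(unname(diag(d$values)), rep(0, 5))

  set.seed(7)
  r <- hellinger_transform(toy_abund(matrix(rpois(60, 8), 6, 10)))
  dr <- bray_curtis(r)
  expect_true(all(dr$values >= 0 & dr$values <= 1))
})

test_that("PCoA reproduces Euclidean geometry exactly and splits the simplex evenly", {
  # colinear points 0, 1, 3: one positive axis carrying ~100% of the variance
  pts <- c(0, 1, 3)
  d <- structure(list(sample_ids = paste0("S", 1:3),
                      values = as.matrix(dist(pts))), class = "dist_matrix")
  ord <- pcoa(d)
  expect_identical(ncol(ord$coordinates), 1L)
  expect_equal(ord$variance_explained[1], 100, tolerance = 1e-9)
  expect_equal(as.matrix(dist(ord$coordinates)), unname(d$values),
               tolerance = 1e-9, ignore_attr = TRUE)

  # three mutually equidistant points: two equal axes at 50% each
  deq <- structure(list(sample_ids = paste0("S", 1:3),
                        values = matrix(1, 3, 3) - diag(3)), class = "dist_matrix")
  oeq <- pcoa(deq)
  expect_equal(oeq$eigenvalues[1], oeq$eigenvalues[2], tolerance = 1e-9)
  expect_equal(oeq$variance_explained[1:2], c(50, 50), tolerance = 1e-9)

  # degenerate all-zero distances: no positive axes
  d0 <- structure(list(sample_ids = paste0("S", 1:4),
                       values = matrix(0, 4, 4)), class = "dist_matrix")
  expect_identical(ncol(pcoa(d0)$coordinates), 0L)

  # classical-scaling exactness on a random Euclidean cloud
  set.seed(3)
  x <- matrix(rnorm(20), 5, 4)
  de <- structure(list(sample_ids = paste0("S", 1:5),
                       values = as.matrix(dist(x))), class = "dist_matrix")
  oe <- pcoa(de)
  expect_equal(as.matrix(dist(oe$coordinates)), unname(de$values),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PERMANOVA matches exhaustive enumeration on a 6-sample toy", {
  set.seed(11)
  x <- rbind(matrix(rnorm(9, 0), 3, 3), matrix(rnorm(9, 1.5), 3, 3))
  dvals <- as.matrix(dist(x))
  rownames(dvals) <- colnames(dvals) <- paste0("S", 1:6)
  d <- structure(list(sample_ids = rownames(dvals), values = dvals),
                 class = "dist_matrix")
  meta <- toy_meta(6, depth = c(5, 5, 5, 23.5, 23.5, 23.5),
                   oxygen = c(rep("oxic", 3), rep("anoxic", 3)))
  fit <- permanova(d, meta, "oxygen", n_perm = 9999, seed = 1)
  oracle <- permanova_enumeration_oracle(dvals, factor(meta$oxygen))
  expect_equal(fit$table$F[1], oracle$f, tolerance = 1e-8)
  # exact p over the 20 assignments vs permutation p (vegan enumerates
  # complete sets at this size)
  expect_lt(abs(fit$table$p[1] - oracle$p), 0.05)
})

test_that("PERMANOVA partitions are a valid decomposition and order-invariant", {
  cfg <- synthetic_config(seed = 21)
  sim <- simulate_dataset(cfg)
  d <- bray_curtis(hellinger_transform(sim$dna))
  fit <- suppressMessages(permanova(d, sim$meta, c("depth_m", "month", "oxygen"),
                                    n_perm = 99, seed = 2))
  expect_equal(sum(fit$table$R2[fit$table$term != "Total"]), 1, tolerance = 1e-9)
  expect_equal(sum(fit$table$Df[fit$table$term != "Total"]), nrow(sim$meta) - 1)
  expect_true(all(fit$table$p >= 1 / 100, na.rm = TRUE))

  # pseudo-F does not depend on sample order
  perm <- sample(16)
  d2 <- structure(list(sample_ids = d$sample_ids[perm],
                       values = d$values[perm, perm]), class = "dist_matrix")
  fit2 <- permanova(d2, sim$meta, c("depth_m", "month", "oxygen"),
                    n_perm = 99, seed = 2)
  expect_equal(fit2$table$F, fit$table$F, tolerance = 1e-10)

  one_level <- toy_meta(6, oxygen = rep("oxic", 6))
  d6 <- structure(list(sample_ids = paste0("S", 1:6),
                       values = as.matrix(dist(rnorm(6)))), class = "dist_matrix")
  expect_error(permanova(d6, one_level, "oxygen", n_perm = 9),
               "single level")
})

test_that("pairwise PERMANOVA covers every level pair and hits the p floor on separated groups", {
  set.seed(5)
  x <- rbind(matrix(rnorm(12, 0, 0.1), 4, 3), matrix(rnorm(12, 10, 0.1), 4, 3),
             matrix(rnorm(12, 20, 0.1), 4, 3))
  dvals <- as.matrix(dist(x))
  rownames(dvals) <- colnames(dvals) <- paste0("S", 1:12)
  d <- structure(list(sample_ids = rownames(dvals), values = dvals),
                 class = "dist_matrix")
  meta <- toy_meta(12, oxygen = rep(c("oxic", "anoxic", "oxycline"), each = 4))
  res <- pairwise_permanova(d, meta, "oxygen", n_perm = 99, seed = 1)
  expect_identical(nrow(res), 3L)
  # near the attainable floor: equivalent relabelings of a balanced 4v4 pair
  # reproduce the observed partition ~1/35 of the time, so p cannot go lower
  expect_true(all(res$p < 0.1))
  expect_true(all(res$R2 > 0.99))
  expect_true(all(res$p_bh >= res$p))

  meta2 <- meta; meta2$oxygen[1:4] <- c("oxic", rep("anoxic", 3))
  # the 1-sample level invalidates both of its pairs
  w <- capture_warnings(pairwise_permanova(d, meta2, "oxygen", n_perm = 9,
                                           seed = 1))
  expect_length(w, 2)
  expect_match(w, "< 2 samples", all = TRUE)
})

test_that("top-taxa prevalence ranks by mean relative abundance with deterministic ties", {
  # hand-built: 3 taxa, 2 conditions (single scheme)
  v <- rbind(c(5, 3, 2), c(7, 1, 2), c(1, 1, 8), c(2, 2, 6))
  m <- tss_normalise(toy_abund(v))
  groups <- data.frame(scheme = "depth", condition = rep(c("depth:5m", "depth:23.5m"), each = 2),
                       sample_id = paste0("S", 1:4), stringsAsFactors = FALSE)
  rep2 <- top_taxa_prevalence(m, groups, k = 2)
  means_a <- colMeans(m$values[1:2, ])
  hand <- names(sort(means_a, decreasing = TRUE))[1:2]
  expect_identical(rep2$top_taxa$taxon_id[rep2$top_taxa$condition == "depth:5m"], hand)

  # a taxon in the top-k of every condition scores Bar_Percent 100
  expect_equal(rep2$prevalence$Bar_Percent[rep2$prevalence$Presence_Count == 2][1], 100)
  expect_true(all(rep2$prevalence$Bar_Percent ==
                  rep2$prevalence$Presence_Count / 2 * 100))

  # fixture-scale report: presence bounded by the number of conditions
  cfg <- synthetic_config(seed = 13)
  sim <- simulate_dataset(cfg)
  g <- assign_condition_groups(sim$meta)
  rep11 <- top_taxa_prevalence(tss_normalise(sim$dna), g, k = 10)
  expect_identical(rep11$n_conditions, 11L)
  expect_true(max(rep11$prevalence$Presence_Count) <= 11)

  empty <- groups[groups$sample_id != "S3" | groups$condition != "depth:23.5m", ]
  expect_error(top_taxa_prevalence(m, data.frame(scheme = "depth",
                                                 condition = "depth:5m",
                                                 sample_id = "missing")),
               "absent")
})
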