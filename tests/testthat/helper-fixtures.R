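# Small builders shared across test files.

toy_abund <- function(values, layer = "dna", normalisation = "raw",
                      samples = NULL, taxa = NULL) {
  v <- as.matrix(values)
  rownames(v) <- samples %||% paste0("S", seq_len(nrow(v)))
  colnames(v) <- taxa %||% paste0("T", seq_len(ncol(v)))
  abundance_matrix(v, layer = layer, normalisation = normalisation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid metadata for n samples, without the generator.
toy_meta <- function(n, depth = rep(c(5, 23.5), length.out = n),
                     month = rep(c("July", "October"), length.out = n),
                     oxygen = rep(c("oxic", "anoxic"), length.out = n)) {
  set.seed(42)
  data.frame(sample_id = paste0("S", seq_len(n)), depth_m = depth,
             month = month, oxygen = oxygen,
             depth = depth, wtemp = 20 - 0.5 * depth + rnorm(n),
             do_sat = runif(n, 0, 100), do_raw = runif(n, 0, 10),
             sp_cond = runif(n, 270, 320), pH = runif(n, 7, 9),
             chlor_rfu = runif(n, 0, 5), phyco_rfu = runif(n, 0, 3),
             fdom_rfu = runif(n, 4, 12), turb_fnu = runif(n, 0.5, 4),
             sampling_time = runif(n, 8, 14),
             stringsAsFactors = FALSE)
}

# Hand-built chain_graph carrying only an edge table (enough for the
# threshold/robustness arithmetic).
fake_chain_graph <- function(weights, u = NULL, v = NULL, kind = NULL) {
  k <- length(weights)
  edges <- data.frame(
    u = u %||% sprintf("A%d", seq_len(k)),
    v = v %||% sprintf("B%d", seq_len(k)),
    weight = weights,
    sign = ifelse(weights >= 0, "positive", "negative"),
    kind = kind %||% rep("taxon-taxon", k),
    stringsAsFactors = FALSE)
  structure(list(edges = edges), class = "chain_graph")
}

# Hand-built permutation ensemble from a vector of per-run focal counts.
fake_ensemble <- function(focal_counts, focal_id = "T1", layer = "dna") {
  runs <- lapply(focal_counts, function(k)
    list(companions = paste0("C", 1:3), threshold = 0.5,
         focal_high_edges = as.integer(k), n_edges = 10L))
  structure(list(focal_id = focal_id, layer = layer,
                 n_permutations = length(focal_counts),
                 companions_per_run = 3L, quantile = 0.9, runs = runs,
                 seed = 1L),
            class = "perm_ensemble")
}

# Independent PERMANOVA oracle: pseudo-F from the Gower matrix, enumerated
# over every assignment of 6 samples to two groups of 3.
permanova_enumeration_oracle <- function(dvals, groups) {
  n <- nrow(dvals)
  gower <- function(D) {
    A <- -0.5 * D^2
    J <- diag(n) - matrix(1 / n, n, n)
    J %*% A %*% J
  }
  G <- gower(dvals)
  f_stat <- function(g) {
    H <- stats::model.matrix(~g)
    H <- H %*% solve(crossprod(H)) %*% t(H)
    ssb <- sum(diag(H %*% G))
    sst <- sum(diag(G))
    df1 <- length(unique(g)) - 1
    (ssb / df1) / ((sst - ssb) / (n - df1 - 1))
  }
  f_obs <- f_stat(groups)
  combos <- utils::combn(n, sum(groups == groups[1]))
  fs <- apply(combos, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    f_stat(factor(g))
  })
  list(f = f_obs, p = mean(fs >= f_obs - 1e-12), all_f = fs)
}

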