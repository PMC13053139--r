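#' Configuration for the synthetic community generator
#'
#' Defines the study conditions the generator emulates: a seasonally sampled
#' stratified lake (16 samples over four depths, four months and three
#' oxygen regimes), a sparse taxon interaction network with a few hub taxa,
#' environmental effects on the hubs, and an expression (RNA) layer whose
#' network can be partially decoupled from the abundance (DNA) layer.
#'
#' @param n_samples number of samples (fixture mode always yields 16).
#' @param n_taxa number of taxa (MAG-level units).
#' @param n_hubs number of planted hub taxa.
#' @param hub_degree spokes per hub in the planted support.
#' @param background_degree target mean (and cap) degree of non-hub taxa.
#' @param library_size_meanlog,library_size_sdlog log-normal parameters of
#'   per-sample sequencing depth (defaults: median 1e4 reads, ~20% spread).
#' @param metadata_mode `"fixture"` reproduces the 16-sample lake design with
#'   its exact group sizes; `"general"` draws an arbitrary grid of
#'   `n_samples`.
#' @param activity_decoupling fraction of RNA-layer edges re-wired relative
#'   to the DNA layer (0 = identical networks).
#' @param env_effect_strength magnitude of planted predictor -> hub effects
#'   on the latent log-abundance scale.
#' @param n_env_links number of predictors linked to each hub.
#' @param predictors names of environmental predictors used for planted
#'   effects and downstream fits.
#' @param seed master integer seed; every stochastic step derives from it.
#' @return A `synth_config` list.
#' @export
synthetic_config <- function(n_samples = 16, n_taxa = 60, n_hubs = 3,
                             hub_degree = 8, background_degree = 2,
                             library_size_meanlog = log(1e4),
                             library_size_sdlog = 0.2,
                             metadata_mode = c("fixture", "general"),
                             activity_decoupling = 0.3,
                             env_effect_strength = 1,
                             n_env_links = 2,
                             predictors = DEFAULT_PREDICTORS,
                             seed = 1) {
  metadata_mode <- match.arg(metadata_mode)
  stopifnot(n_samples >= 1, n_taxa >= 2, n_hubs >= 0, hub_degree >= 1,
            background_degree >= 0,
            activity_decoupling >= 0, activity_decoupling <= 1)
  structure(list(n_samples = n_samples, n_taxa = n_taxa, n_hubs = n_hubs,
                 hub_degree = hub_degree, background_degree = background_degree,
                 library_size_meanlog = library_size_meanlog,
                 library_size_sdlog = library_size_sdlog,
                 metadata_mode = metadata_mode,
                 activity_decoupling = activity_decoupling,
                 env_effect_strength = env_effect_strength,
                 n_env_links = n_env_links,
                 predictors = predictors, seed = seed),
            class = "synth_config")
}

# Sparse support with hub-and-spoke plus capped background edges. Non-hub
# degree never exceeds background_degree, hubs get exactly hub_degree spokes.
build_support <- function(p, n_hubs, hub_degree, background_degree) {
  adj <- matrix(0L, p, p)
  hubs <- integer(0)
  nonhub <- seq_len(p)
  if (n_hubs > 0) {
    hubs <- sample(p, n_hubs)
    nonhub <- setdiff(seq_len(p), hubs)
    if (hub_degree > length(nonhub) ||
        n_hubs * hub_degree > length(nonhub) * background_degree)
      stop("infeasible degree demands: not enough non-hub capacity")
    cap <- rep(background_degree, p)
    for (h in hubs) {
      avail <- nonhub[cap[nonhub] > 0 & adj[h, nonhub] == 0]
      if (length(avail) < hub_degree) stop("infeasible degree demands")
      partners <- sample(avail, hub_degree)
      adj[h, partners] <- adj[partners, h] <- 1L
      cap[partners] <- cap[partners] - 1L
    }
  }
  # background edges among non-hubs up to the degree cap
  n_spokes <- n_hubs * hub_degree
  target_bg <- max(0, round((background_degree * length(nonhub) - n_spokes) / 2))
  cap <- rep(background_degree, p)
  deg <- colSums(adj)
  attempts <- 0
  added <- 0
  while (added < target_bg && attempts < 50 * max(1, target_bg)) {
    attempts <- attempts + 1
    uv <- sample(nonhub, 2)
    u <- uv[1]; v <- uv[2]
    if (adj[u, v] == 0 && deg[u] < cap[u] && deg[v] < cap[v]) {
      adj[u, v] <- adj[v, u] <- 1L
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      added <- added + 1
    }
  }
  list(adjacency = adj, hubs = hubs)
}

# Signed edge magnitudes in [0.2, 0.5]; positive definiteness enforced by a
# uniform diagonal shift past the most negative eigenvalue of the edge
# matrix, so every edge keeps a comparable planted partial correlation
# (row-wise dominance would dilute hub edges in proportion to hub degree).
support_to_precision <- function(adj, values = NULL, margin = 0.2) {
  p <- nrow(adj)
  theta <- matrix(0, p, p)
  idx <- which(upper.tri(adj) & adj == 1L)
  if (is.null(values)) {
    values <- stats::runif(length(idx), 0.2, 0.5) *
      sample(c(-1, 1), length(idx), replace = TRUE)
  }
  theta[idx] <- values
  theta <- theta + t(theta)
  ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  diag(theta) <- abs(ev_min) + margin
  theta
}

# Degree-preserving double-edge swaps on a fraction of edges; carried edge
# values stay with surviving edges, new edges draw fresh values.
rewire_support <- function(adj, frac) {
  p <- nrow(adj)
  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  n_e <- nrow(edges)
  if (n_e < 2 || frac <= 0) return(adj)
  target <- ceiling(frac * n_e / 2)  # each swap re-wires two edges
  done <- 0; attempts <- 0
  while (done < target && attempts < 100 * target) {
    attempts <- attempts + 1
    pick <- sample(n_e, 2)
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
    if (length(unique(c(a, b, c_, d))) < 4) next
    if (adj[a, d] == 1L || adj[c_, b] == 1L) next
    adj[a, b] <- adj[b, a] <- 0L
    adj[c_, d] <- adj[d, c_] <- 0L
    adj[a, d] <- adj[d, a] <- 1L
    adj[c_, b] <- adj[b, c_] <- 1L
    edges[pick[1], ] <- c(min(a, d), max(a, d))
    edges[pick[2], ] <- c(min(c_, b), max(c_, b))
    done <- done + 1
  }
  adj
}

#' Generate a planted interaction network with ground truth
#'
#' Builds a sparse precision matrix over taxa (hub-and-spoke plus a capped
#' random background), assigns signed edge magnitudes in \[0.2, 0.5\],
#' enforces positive definiteness by diagonal dominance, plants
#' environmental effects on the hub taxa, and derives the RNA-layer support
#' by degree-preserving re-wiring of a fraction `activity_decoupling` of
#' edges. Everything is recorded so downstream recovery is testable.
#'
#' @param cfg a [synthetic_config()].
#' @return A `planted_network` list with taxon ids, DNA/RNA precision and
#'   adjacency matrices, hub ids, per-taxon baseline means, and the
#'   predictors-by-taxa `env_effects` matrix.
#' @export
generate_planted_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- cfg$n_taxa
  if (cfg$n_hubs * cfg$hub_degree >= p * (p - 1) / 2)
    stop("infeasible degree demands")
  with_seed(derive_seed(cfg$seed, "network"), {
    taxa <- sprintf("MAG_%03d", seq_len(p))
    sup <- build_support(p, cfg$n_hubs, cfg$hub_degree, cfg$background_degree)
    theta_dna <- support_to_precision(sup$adjacency)
    adj_rna <- rewire_support(sup$adjacency, cfg$activity_decoupling)
    theta_rna <- support_to_precision(adj_rna)
    dimnames(theta_dna) <- dimnames(theta_rna) <- list(taxa, taxa)
    adj_dna <- sup$adjacency
    dimnames(adj_dna) <- dimnames(adj_rna) <- list(taxa, taxa)
    base <- stats::rnorm(p, 0, 1)
    names(base) <- taxa
    P <- length(cfg$predictors)
    env_effects <- matrix(0, P, p, dimnames = list(cfg$predictors, taxa))
    for (h in sup$hubs) {
      links <- sample(P, min(cfg$n_env_links, P))
      env_effects[links, h] <- cfg$env_effect_strength *
        sample(c(-1, 1), length(links), replace = TRUE)
    }
    structure(list(taxon_ids = taxa,
                   precision_dna = theta_dna, adjacency_dna = adj_dna,
                   precision_rna = theta_rna, adjacency_rna = adj_rna,
                   hub_ids = taxa[sup$hubs], base = base,
                   env_effects = env_effects, seed = cfg$seed, cfg = cfg),
              class = "planted_network")
  })
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted_network> %d taxa, %d hubs, %d DNA edges, %d RNA edges\n",
              length(x$taxon_ids), length(x$hub_ids),
              sum(x$adjacency_dna[upper.tri(x$adjacency_dna)]),
              sum(x$adjacency_rna[upper.tri(x$adjacency_rna)])))
  invisible(x)
}

# The 16-sample stratified-lake fixture: 4 depths (2/2/6/6), 4 months
# (3/6/2/5), 3 oxygen regimes (4/9/3) = 11 conditions.
fixture_design <- function() {
  d <- function(date, depth, oxy) list(date = date, depth = depth, oxy = oxy)
  rows <- list(
    d("2020-07-16", 5,    "oxic"),
    d("2020-07-16", 10,   "oxycline"),
    d("2020-07-16", 23.5, "anoxic"),
    d("2020-08-05", 10,   "oxycline"),
    d("2020-08-11", 15,   "anoxic"),
    d("2020-08-11", 23.5, "anoxic"),
    d("2020-08-18", 15,   "anoxic"),
    d("2020-08-25", 15,   "anoxic"),
    d("2020-08-25", 23.5, "anoxic"),
    d("2020-09-11", 15,   "anoxic"),
    d("2020-09-11", 23.5, "anoxic"),
    d("2020-10-08", 15,   "oxycline"),
    d("2020-10-08", 23.5, "anoxic"),
    d("2020-10-19", 5,    "oxic"),
    d("2020-10-19", 15,   "oxic"),
    d("2020-10-19", 23.5, "oxic"))
  data.frame(date = vapply(rows, `[[`, "", "date"),
             depth_m = vapply(rows, `[[`, 0, "depth"),
             oxygen = vapply(rows, `[[`, "", "oxy"),
             stringsAsFactors = FALSE)
}

month_name <- function(date) {
  format(as.Date(date), "%B")
}

# Depth/oxygen/season-dependent sonde profiles. Each variable carries
# substantial variable-specific variation on top of the shared
# depth/season/oxygen structure (internal waves, blooms, storms), so
# planted predictor effects remain statistically identifiable; real lake
# profiles are typically more collinear.
draw_env <- function(depth, oxygen, month_idx) {
  n <- length(depth)
  wtemp <- pmax(4, 26 - 0.55 * depth - 1.2 * (month_idx - 1) + stats::rnorm(n, 0, 3))
  do_raw <- ifelse(oxygen == "oxic", pmax(4, 8.5 + stats::rnorm(n, 0, 1.5)),
            ifelse(oxygen == "oxycline", pmax(0.3, 3 + stats::rnorm(n, 0, 1.2)),
                   0.15 + abs(stats::rnorm(n, 0, 0.1))))
  data.frame(
    depth = depth,
    wtemp = wtemp,
    do_sat = pmax(0, do_raw * 11 + stats::rnorm(n, 0, 8)),
    do_raw = do_raw,
    sp_cond = 280 + 1.2 * depth + stats::rnorm(n, 0, 12),
    pH = 8.7 - 0.06 * depth + stats::rnorm(n, 0, 0.35),
    chlor_rfu = pmax(0, 1 + 4 * exp(-depth / 8) + stats::rnorm(n, 0, 1.2)),
    phyco_rfu = pmax(0, 0.5 + 2 * exp(-abs(depth - 10) / 6) + stats::rnorm(n, 0, 0.7)),
    fdom_rfu = 5 + 0.25 * depth + stats::rnorm(n, 0, 1.8),
    turb_fnu = 1 + 0.08 * depth + abs(stats::rnorm(n, 0, 0.8)),
    sampling_time = stats::runif(n, 8, 14))
}

#' Generate sample metadata
#'
#' Fixture mode reproduces the reference 16-sample stratified-lake design
#' exactly: depths 5/10/15/23.5 m with group sizes 2/2/6/6, months
#' July-October with sizes 3/6/2/5, oxygen regimes oxic/anoxic/oxycline with
#' sizes 4/9/3 (11 conditions in total). General mode draws `n_samples` from
#' the same grid with depth-consistent oxygen regimes. Continuous sonde
#' variables are drawn from depth-, season- and oxygen-dependent ranges.
#'
#' @param cfg a [synthetic_config()].
#' @return A validated metadata data.frame.
#' @export
generate_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(derive_seed(cfg$seed, "metadata"), {
    if (cfg$metadata_mode == "fixture") {
      des <- fixture_design()
    } else {
      depth <- sample(c(5, 10, 15, 23.5), cfg$n_samples, replace = TRUE)
      oxygen <- vapply(depth, function(d) {
        if (d <= 10) sample(c("oxic", "oxycline"), 1, prob = c(0.85, 0.15))
        else if (d <= 15) sample(c("oxycline", "anoxic"), 1, prob = c(0.4, 0.6))
        else sample(c("anoxic", "oxic"), 1, prob = c(0.9, 0.1))
      }, character(1))
      mo <- sample(sprintf("2020-%02d-15", 7:10), cfg$n_samples, replace = TRUE)
      des <- data.frame(date = mo, depth_m = depth, oxygen = oxygen,
                        stringsAsFactors = FALSE)
    }
    month <- month_name(des$date)
    midx <- match(month, c("July", "August", "September", "October"))
    env <- draw_env(des$depth_m, des$oxygen, midx)
    id <- sprintf("%s_%02d_D%s_%s", substr(month, 1, 3),
                  seq_len(nrow(des)), des$depth_m, des$oxygen)
    meta <- data.frame(sample_id = id, date = des$date, depth_m = des$depth_m,
                       month = month, oxygen = des$oxygen, env,
                       stringsAsFactors = FALSE)
    validate_metadata(meta)
    meta
  })
}

#' Simulate a count matrix from a planted network
#'
#' Logistic-normal-multinomial sampling: the latent per-sample log-abundance
#' vector is multivariate normal with covariance equal to the inverse of the
#' planted precision matrix and mean shifted by `env_effects` times the
#' min-max-scaled predictors; counts are then drawn multinomially with a
#' log-normal library size. The planted precision matrix is thus the literal
#' ground truth of the latent layer. For `layer = "rna"` the re-wired
#' RNA-layer precision generates the latent field, so a taxon can be
#' abundant yet transcriptionally quiet.
#'
#' @param net a [generate_planted_network()] result.
#' @param meta metadata for the samples to simulate.
#' @param layer `"dna"` or `"rna"`.
#' @param cfg the [synthetic_config()] (library-size parameters).
#' @param seed optional seed override; defaults to a layer-specific stream
#'   derived from `cfg$seed`.
#' @return A raw-layer [abundance_matrix()].
#' @export
simulate_counts <- function(net, meta, layer = c("dna", "rna"), cfg = net$cfg,
                            seed = NULL) {
  layer <- match.arg(layer)
  stopifnot(inherits(net, "planted_network"))
  validate_metadata(meta, env_vars = rownames(net$env_effects))
  theta <- if (layer == "dna") net$precision_dna else net$precision_rna
  p <- ncol(theta)
  n <- nrow(meta)
  X <- env_matrix(meta, predictors = rownames(net$env_effects), scale = TRUE)
  if (ncol(X) != nrow(net$env_effects)) stop("mismatched predictor dimensions")
  # planted coefficients are per standard deviation of the scaled predictor,
  # so "strength 1" always means one latent log-unit per predictor SD
  X <- scale(X)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, paste0("counts_", layer))
  with_seed(seed, {
    sigma <- chol2inv(chol(theta))
    R <- chol(sigma)
    mu <- matrix(net$base, n, p, byrow = TRUE) + X %*% net$env_effects
    z <- mu + matrix(stats::rnorm(n * p), n, p) %*% R
    probs <- exp(z - apply(z, 1, max))
    probs <- probs / rowSums(probs)
    lib <- pmax(100, round(stats::rlnorm(n, cfg$library_size_meanlog,
                                         cfg$library_size_sdlog)))
    counts <- t(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, lib[i], probs[i, ])[, 1],
                       numeric(p)))
    dimnames(counts) <- list(meta$sample_id, net$taxon_ids)
    abundance_matrix(counts, layer = layer, normalisation = "raw")
  })
}

#' Generate a synthetic taxonomy with rank-dependent resolution
#'
#' Emulates the usual decline of taxonomic resolution toward finer ranks:
#' each record draws one uniform variate and a rank is UNKNOWN when that
#' variate falls below the rank's unknown rate, so unknown-ness is
#' automatically monotone down the hierarchy when the rates are
#' non-decreasing with depth.
#'
#' @param n_taxa number of records.
#' @param unknown_rates named numeric vector over the seven ranks,
#'   non-decreasing with depth, each in \[0, 1\]. The default mirrors a MAG
#'   catalogue where nearly everything resolves to order but only ~10%
#'   resolves to species.
#' @param seed integer seed.
#' @return data.frame of taxonomy records (see [read_taxonomy()]).
#' @export
generate_taxonomy <- function(n_taxa,
                              unknown_rates = c(domain = 0, phylum = 0,
                                                class = 0, order = 0.003,
                                                family = 0.033, genus = 0.19,
                                                species = 0.9),
                              seed = 1) {
  unknown_rates <- unknown_rates[TAXONOMIC_RANKS]
  if (any(is.na(unknown_rates))) stop("unknown_rates must name all seven ranks")
  if (any(unknown_rates < 0 | unknown_rates > 1))
    stop("unknown_rates must lie in [0, 1]")
  if (any(diff(unknown_rates) < 0))
    stop("unknown_rates must be non-decreasing with rank depth")
  pool <- c(domain = 2, phylum = 27, class = 54, order = 104, family = 151,
            genus = 176, species = 431)
  with_seed(derive_seed(seed, "taxonomy"), {
    u <- stats::runif(n_taxa)
    rk <- matrix("UNKNOWN", n_taxa, length(TAXONOMIC_RANKS),
                 dimnames = list(NULL, TAXONOMIC_RANKS))
    for (j in seq_along(TAXONOMIC_RANKS)) {
      r <- TAXONOMIC_RANKS[j]
      known <- u >= unknown_rates[j]
      lab <- paste0(substr(r, 1, 1), "_",
                    sample.int(pool[[r]], n_taxa, replace = TRUE))
      if (r == "species") lab <- paste0("s_sp", seq_len(n_taxa))
      rk[known, j] <- lab[known]
    }
    tax <- data.frame(taxon_id = sprintf("MAG_%03d", seq_len(n_taxa)), rk,
                      stringsAsFactors = FALSE)
    enforce_rank_monotonicity(tax)
  })
}

#' Simulate a full paired dataset
#'
#' Convenience wrapper: metadata, planted network, DNA and RNA count
#' matrices and taxonomy from one config.
#'
#' @param cfg a [synthetic_config()].
#' @return List with elements `meta`, `network`, `dna`, `rna`, `taxonomy`,
#'   `cfg`.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  meta <- generate_metadata(cfg)
  net <- generate_planted_network(cfg)
  list(meta = meta, network = net,
       dna = simulate_counts(net, meta, "dna", cfg),
       rna = simulate_counts(net, meta, "rna", cfg),
       taxonomy = generate_taxonomy(cfg$n_taxa, seed = cfg$seed),
       cfg = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits the same TSV dialects the readers accept, plus a ground-truth JSON
#' (planted edges, hubs, environmental effects) for test harnesses.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(sim$dna, file.path(dir, "abundance_dna.tsv"))
  write_abundance_table(sim$rna, file.path(dir, "abundance_rna.tsv"))
  utils::write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  net <- sim$network
  edge_list <- function(adj) {
    e <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    data.frame(u = rownames(adj)[e[, 1]], v = colnames(adj)[e[, 2]])
  }
  truth <- list(hub_ids = net$hub_ids,
                edges_dna = edge_list(net$adjacency_dna),
                edges_rna = edge_list(net$adjacency_rna),
                env_effects = as.data.frame(net$env_effects),
                seed = net$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
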