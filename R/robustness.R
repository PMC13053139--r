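#' Edges above the high-connectivity threshold of a chain graph
#'
#' The threshold is the empirical quantile (linear interpolation) of the
#' absolute edge weights over *all* edges of the graph — taxon-taxon and
#' env-taxon alike — and an edge is "high-connectivity" when its absolute
#' weight lies strictly above that threshold (so if all weights are equal,
#' nothing qualifies).
#'
#' @param g a `chain_graph`.
#' @param quantile quantile level in \[0, 1) (default 0.90).
#' @param pool `"all"` (default) or `"taxon-taxon"` to restrict the edge
#'   pool the threshold is computed over.
#' @return List with `edges` (the qualifying subset of `g$edges`) and
#'   `threshold` (`NA` for an empty graph).
#' @export
high_connectivity_edges <- function(g, quantile = 0.90, pool = c("all", "taxon-taxon")) {
  stopifnot(inherits(g, "chain_graph"), quantile >= 0, quantile < 1)
  pool <- match.arg(pool)
  e <- g$edges
  if (pool == "taxon-taxon") e <- e[e$kind == "taxon-taxon", , drop = FALSE]
  if (nrow(e) == 0)
    return(list(edges = e, threshold = NA_real_))
  thr <- stats::quantile(abs(e$weight), probs = quantile, names = FALSE, type = 7)
  list(edges = e[abs(e$weight) > thr, , drop = FALSE], threshold = thr)
}

#' Re-assemble communities around a focal taxon and refit the chain graph
#'
#' The permutation procedure behind the connectivity robustness index: the
#' focal taxon is retained and combined with `n_companions` taxa drawn
#' uniformly without replacement from the pool; a chain graph with all
#' predictors is fitted to each re-assembled community; each run's
#' high-connectivity threshold is the configured quantile of that run's
#' absolute edge-weight distribution, and the number of focal edges
#' strictly above it is recorded.
#'
#' @param focal_id the focal taxon.
#' @param pool candidate companion taxa (must exclude `focal_id` and have at
#'   least `n_companions` members).
#' @param m raw-layer [abundance_matrix()] covering focal and pool taxa.
#' @param meta per-sample metadata.
#' @param n_perm number of re-assembled communities (default 100).
#' @param n_companions companions per run (default 14, giving the
#'   conventional 15-taxon response set).
#' @param quantile threshold quantile (default 0.90).
#' @param chain_cfg list of [fit_chain_graph()] settings
#'   (`predictor_names`, `lambda_b`, `lambda_omega`).
#' @param seed integer master seed; companion draws are independent across
#'   runs via derived sub-seeds.
#' @param keep_graphs retain each run's fitted `chain_graph` (memory-heavy;
#'   useful for diagnostics and null-calibration checks).
#' @param threshold_pool edge pool the per-run quantile threshold is taken
#'   over: `"all"` (default; taxon-taxon and env-taxon together) or
#'   `"taxon-taxon"`. With few samples the penalised env coefficients can
#'   dominate the pooled weight distribution; restricting the pool makes the
#'   threshold a purely biotic reference.
#' @return A `perm_ensemble`: per-run companions, thresholds and focal
#'   high-connectivity edge counts.
#' @export
run_permutation_ensemble <- function(focal_id, pool, m, meta, n_perm = 100,
                                     n_companions = 14, quantile = 0.90,
                                     chain_cfg = list(), seed = 1,
                                     keep_graphs = FALSE,
                                     threshold_pool = c("all", "taxon-taxon")) {
  threshold_pool <- match.arg(threshold_pool)
  stopifnot(inherits(m, "abund_mat"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  pool <- setdiff(pool, focal_id)
  if (length(pool) < n_companions)
    stop("pool too small: ", length(pool), " candidates for ",
         n_companions, " companions")
  if (!focal_id %in% taxon_ids(m)) stop("focal taxon absent from matrix")
  runs <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    companions <- with_seed(derive_seed(seed, paste0("draw_", r)),
                            sample(pool, n_companions))
    sub <- abundance_matrix(m$values[, c(focal_id, companions), drop = FALSE],
                            layer = m$layer, normalisation = "raw")
    g <- fit_chain_graph(sub, meta,
                         predictor_names = chain_cfg$predictor_names,
                         lambda_b = chain_cfg$lambda_b,
                         lambda_omega = chain_cfg$lambda_omega,
                         seed = derive_seed(seed, paste0("fit_", r)))
    hc <- high_connectivity_edges(g, quantile, pool = threshold_pool)
    n_focal <- if (nrow(hc$edges))
      sum(hc$edges$u == focal_id | hc$edges$v == focal_id) else 0L
    runs[[r]] <- list(companions = companions, threshold = hc$threshold,
                      focal_high_edges = as.integer(n_focal),
                      n_edges = nrow(g$edges),
                      graph = if (keep_graphs) g else NULL)
  }
  structure(list(focal_id = focal_id, layer = m$layer, n_permutations = n_perm,
                 companions_per_run = n_companions, quantile = quantile,
                 threshold_pool = threshold_pool, runs = runs, seed = seed),
            class = "perm_ensemble")
}

#' @export
print.perm_ensemble <- function(x, ...) {
  cat(sprintf("<perm_ensemble> focal=%s layer=%s, %d runs, index = %.1f%%\n",
              x$focal_id, x$layer, x$n_permutations,
              connectivity_robustness_index(x)))
  invisible(x)
}

#' Connectivity robustness index
#'
#' Percentage of permutation runs (0-100%) in which the focal taxon is an
#' endpoint of at least one high-connectivity edge. High values mean the
#' taxon keeps its central network role regardless of which companions are
#' present — the signature of a keystone taxon.
#'
#' @param ensemble a [run_permutation_ensemble()] result.
#' @return Percentage in \[0, 100\].
#' @export
connectivity_robustness_index <- function(ensemble) {
  stopifnot(inherits(ensemble, "perm_ensemble"))
  hit <- vapply(ensemble$runs, function(r) r$focal_high_edges >= 1, logical(1))
  100 * sum(hit) / ensemble$n_permutations
}

#' Compare the abundance and expression layers of a focal taxon
#'
#' Classifies a taxon by whether its connectivity robustness index clears
#' the cutoff in the DNA (abundance) layer, the RNA (expression) layer,
#' both, or neither. A taxon that is robustly central in both layers is
#' not only structurally embedded but also transcriptionally active — the
#' strongest keystone evidence.
#'
#' @param dna,rna `perm_ensemble`s for the same focal taxon in the two
#'   layers.
#' @param cutoff index cutoff in percent (default 30; a reporting
#'   convention, not an inference — raw indices are always returned).
#' @return A `robustness_result`: `focal_id`, `index_dna`, `index_rna`,
#'   `classification` (one of `active_keystone`, `abundance_only`,
#'   `activity_only`, `not_keystone`) and `cutoff`.
#' @export
compare_layers <- function(dna, rna, cutoff = 30) {
  stopifnot(inherits(dna, "perm_ensemble"), inherits(rna, "perm_ensemble"))
  if (dna$focal_id != rna$focal_id)
    stop("focal mismatch: ", dna$focal_id, " vs ", rna$focal_id)
  idx_d <- connectivity_robustness_index(dna)
  idx_r <- connectivity_robustness_index(rna)
  cls <- if (idx_d >= cutoff && idx_r >= cutoff) "active_keystone"
         else if (idx_d >= cutoff) "abundance_only"
         else if (idx_r >= cutoff) "activity_only"
         else "not_keystone"
  structure(list(focal_id = dna$focal_id, index_dna = idx_d, index_rna = idx_r,
                 classification = cls, cutoff = cutoff),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("%s: DNA %.0f%% / RNA %.0f%% (cutoff %.0f%%) -> %s\n",
              x$focal_id, x$index_dna, x$index_rna, x$cutoff,
              x$classification))
  invisible(x)
}

#' Summarise a permutation ensemble as a table
#'
#' @param ensemble a `perm_ensemble`.
#' @return data.frame `run`, `threshold`, `focal_high_edges`, `n_edges`,
#'   `companions` (semicolon-joined).
#' @export
ensemble_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "perm_ensemble"))
  data.frame(run = seq_len(ensemble$n_permutations),
             threshold = vapply(ensemble$runs, `[[`, 0, "threshold"),
             focal_high_edges = vapply(ensemble$runs, `[[`, 0L, "focal_high_edges"),
             n_edges = vapply(ensemble$runs, function(r) as.integer(r$n_edges), 0L),
             companions = vapply(ensemble$runs,
                                 function(r) paste(r$companions, collapse = ";"), ""),
             stringsAsFactors = FALSE)
}
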