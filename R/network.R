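#' Graphical lasso fit
#'
#' Estimates a sparse precision (inverse covariance) matrix by maximising
#' the L1-penalised Gaussian log-likelihood, using block coordinate descent
#' over columns of the working covariance. Zero off-diagonal entries of the
#' precision matrix encode conditional independence between taxa.
#'
#' @param S covariance matrix (symmetric).
#' @param lambda L1 penalty (non-negative scalar).
#' @param tol relative convergence tolerance on the working covariance.
#' @param maxit maximum outer sweeps.
#' @return List with `theta` (precision), `w` (estimated covariance),
#'   `niter`, `converged`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, maxit = 200) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), lambda >= 0)
  out <- glasso_fit_cpp(S, lambda, tol, maxit)
  dimnames(out$theta) <- dimnames(out$w) <- dimnames(S)
  out
}

#' @rdname glasso_fit
#' @param lambdas strictly decreasing penalty sequence; fits are warm-started
#'   from the previous penalty.
#' @return For `glasso_path`: list of precision matrices, one per penalty.
#' @export
glasso_path <- function(S, lambdas, tol = 1e-4, maxit = 200) {
  S <- as.matrix(S)
  if (any(diff(lambdas) >= 0)) stop("lambda path must be strictly decreasing")
  out <- glasso_path_cpp(S, lambdas, tol, maxit)
  lapply(out$thetas, function(th) {
    dimnames(th) <- dimnames(S)
    th
  })
}

# Support of a precision matrix (off-diagonal, symmetric binary).
precision_support <- function(theta, zero_tol = 1e-10) {
  adj <- (abs(theta) > zero_tol) * 1L
  diag(adj) <- 0L
  adj
}

# Signed partial correlations: -theta_ij / sqrt(theta_ii * theta_jj).
partial_correlations <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / outer(d, d)
  diag(pc) <- 0
  pc
}

default_lambda_path <- function(S, n_lambda = 30, min_ratio = 0.01) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Sparse co-occurrence network by glasso with StARS selection
#'
#' The compositional route to a taxon co-occurrence network: counts are
#' CLR-transformed, the correlation matrix of the CLR coordinates is fed to
#' the graphical lasso along a descending penalty path, and the penalty is
#' selected by StARS (Stability Approach to Regularisation Selection) —
#' edge-selection instability is measured over random subsamples, the
#' instability curve is monotonised from the sparse end, and the smallest
#' penalty whose monotonised instability stays within `stars_beta` is
#' selected (the densest graph that is still reproducible under
#' subsampling). Edge weights are the signed partial correlations of the
#' selected precision matrix.
#'
#' @param m raw-layer [abundance_matrix()] with >= 4 samples and >= 2 taxa.
#' @param lambda_path descending penalty sequence; defaults to `n_lambda`
#'   log-spaced points from the maximal absolute off-diagonal covariance
#'   down to 1% of it.
#' @param n_lambda,lambda_min_ratio default path parameters.
#' @param stars_subsamples number of random subsamples (default 50).
#' @param stars_ratio subsample fraction; default 0.8 for n <= 144 and
#'   `10 sqrt(n) / n` for larger n.
#' @param stars_beta instability threshold (default 0.05).
#' @param pseudocount CLR pseudocount (default 1).
#' @param seed integer seed for the subsampling.
#' @return A `cooccur_network`: taxon ids, binary adjacency, signed
#'   partial-correlation weights, the selected penalty and the stability
#'   path summary.
#' @export
spiec_easi_network <- function(m, lambda_path = NULL, n_lambda = 30,
                               lambda_min_ratio = 0.01,
                               stars_subsamples = 50, stars_ratio = NULL,
                               stars_beta = 0.05, pseudocount = 1, seed = 1) {
  stopifnot(inherits(m, "abund_mat"))
  n <- nrow(m$values); p <- ncol(m$values)
  if (n < 4) stop("need at least 4 samples")
  if (p < 2) stop("need at least 2 taxa")
  x <- clr_transform(m, pseudocount)$values
  # correlation scale so one penalty treats all taxon pairs comparably
  S <- stats::cor(x)
  if (is.null(lambda_path)) {
    lambda_path <- default_lambda_path(S, n_lambda, lambda_min_ratio)
  } else if (any(diff(lambda_path) >= 0)) {
    stop("lambda path must be strictly decreasing")
  }
  if (is.null(stars_ratio)) stars_ratio <- if (n <= 144) 0.8 else 10 * sqrt(n) / n
  b <- ceiling(stars_ratio * n)
  if (b < 3) stop("subsample size < 3; increase stars_ratio or sample size")
  L <- length(lambda_path)
  n_pairs <- p * (p - 1) / 2
  edge_freq <- matrix(0, L, n_pairs)
  with_seed(derive_seed(seed, "stars"), {
    for (s in seq_len(stars_subsamples)) {
      idx <- sample(n, b)
      Ssub <- stats::cor(x[idx, , drop = FALSE])
      thetas <- glasso_path(Ssub, lambda_path)
      for (l in seq_len(L)) {
        adj <- precision_support(thetas[[l]])
        edge_freq[l, ] <- edge_freq[l, ] + adj[upper.tri(adj)]
      }
    }
  })
  freq <- edge_freq / stars_subsamples
  instability <- rowMeans(2 * freq * (1 - freq))
  mono <- cummax(instability)  # from largest penalty toward smallest
  ok <- which(mono <= stars_beta)
  sel <- if (length(ok)) max(ok) else 1L
  theta <- glasso_fit(S, lambda_path[sel])$theta
  adj <- precision_support(theta)
  w <- partial_correlations(theta) * adj
  structure(list(taxon_ids = colnames(m$values), adjacency = adj,
                 edge_weights = w, selected_lambda = lambda_path[sel],
                 lambda_path = lambda_path, instability = instability,
                 monotone_instability = mono, stars_beta = stars_beta,
                 stars_subsamples = stars_subsamples, subsample_size = b,
                 seed = seed),
            class = "cooccur_network")
}

#' @export
print.cooccur_network <- function(x, ...) {
  cat(sprintf("<cooccur_network> %d taxa, %d edges, lambda = %.4g\n",
              length(x$taxon_ids), sum(x$adjacency[upper.tri(x$adjacency)]),
              x$selected_lambda))
  invisible(x)
}

#' Rank taxa by degree centrality
#'
#' Degree centrality — the number of edges incident to a taxon — is the
#' selection criterion for influential taxa. Ties are broken by taxon id so
#' the ranking is deterministic.
#'
#' @param net a `cooccur_network`.
#' @return data.frame `taxon_id`, `degree`, sorted by non-increasing degree
#'   then id.
#' @export
degree_rank <- function(net) {
  stopifnot(inherits(net, "cooccur_network"))
  deg <- colSums(net$adjacency)
  out <- data.frame(taxon_id = net$taxon_ids, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-k taxa of a degree ranking
#'
#' @param ranking output of [degree_rank()].
#' @param k number of taxa to keep (default 15, the conventional cut for
#'   downstream chain-graph analysis).
#' @return Character vector of taxon ids (all of them, with a warning, when
#'   fewer than `k` are ranked).
#' @export
select_top_k <- function(ranking, k = 15) {
  stopifnot(k >= 1)
  if (nrow(ranking) < k) {
    warning("only ", nrow(ranking), " taxa available; returning all")
    return(ranking$taxon_id)
  }
  ranking$taxon_id[seq_len(k)]
}
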