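// Graphical lasso: L1-penalised sparse inverse-covariance estimation by
// block coordinate descent (one lasso subproblem per column of the working
// covariance), with warm starts along a penalty path. The inner lasso keeps
// the running product q = W11 * beta so each coordinate update is O(p).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso fit for covariance S at penalty lambda, warm-started from W
// (working covariance) and B (p x p per-column lasso coefficients,
// B(j,j) == 0).
static void glasso_one(const mat& S, double lambda, mat& W, mat& B,
                       double tol, int maxit, int& niter, bool& converged) {
  const uword p = S.n_rows;
  const double offmean = p > 1 ? accu(abs(S - diagmat(S))) / (double)(p * (p - 1)) : 0.0;
  const double thr = tol * std::max(offmean, 1e-12);

  vec beta(p), q(p);
  converged = false;
  niter = 0;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      beta = B.col(j);
      beta(j) = 0.0;
      // q = W * beta over columns l != j (entry j of q is unused)
      q.zeros();
      for (uword l = 0; l < p; ++l)
        if (l != j && beta(l) != 0.0) q += W.col(l) * beta(l);
      for (int in_it = 0; in_it < 200; ++in_it) {
        double del = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j) - (q(k) - W(k, k) * beta(k));
          double bnew = soft(grad, lambda) / W(k, k);
          double d = bnew - beta(k);
          if (d != 0.0) {
            beta(k) = bnew;
            q += W.col(k) * d;
            double ad = std::fabs(d);
            if (ad > del) del = ad;
          }
        }
        if (del < 1e-7) break;
      }
      B.col(j) = beta;
      B(j, j) = 0.0;
      // w12 = W11 * beta is exactly q (ignoring entry j)
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::fabs(q(k) - W(k, j));
        if (d > maxdiff) maxdiff = d;
        W(k, j) = q(k);
        W(j, k) = q(k);
      }
    }
    niter = it + 1;
    if (maxdiff < thr) { converged = true; break; }
  }
}

// Recover the precision matrix from the converged W and B.
static mat recover_theta(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double dot = 0.0;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      dot += W(k, j) * B(k, j);
    }
    double tjj = 1.0 / (W(j, j) - dot);
    theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      theta(k, j) = -B(k, j) * tjj;
    }
  }
  return 0.5 * (theta + theta.t());
}

// [[Rcpp::export]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda,
                          double tol = 1e-4, int maxit = 200) {
  mat W = S;
  W.diag() += lambda;
  mat B(S.n_rows, S.n_rows, fill::zeros);
  int niter; bool converged;
  glasso_one(S, lambda, W, B, tol, maxit, niter, converged);
  mat theta = recover_theta(W, B);
  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = theta,
                            Rcpp::Named("niter") = niter,
                            Rcpp::Named("converged") = converged);
}

// Path version, warm-started from the previous (larger) lambda.
// lambdas must be strictly decreasing.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-4, int maxit = 200) {
  const uword p = S.n_rows, L = lambdas.n_elem;
  mat W = S;
  W.diag() += lambdas(0);
  mat B(p, p, fill::zeros);
  Rcpp::List thetas(L);
  Rcpp::IntegerVector iters(L);
  for (uword i = 0; i < L; ++i) {
    if (i > 0) {
      // refresh the diagonal for the new penalty, keep off-diagonal warm
      W.diag() = S.diag() + lambdas(i);
    }
    int niter; bool converged;
    glasso_one(S, lambdas(i), W, B, tol, maxit, niter, converged);
    thetas[i] = Rcpp::wrap(recover_theta(W, B));
    iters[i] = niter;
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("niter") = iters);
}
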