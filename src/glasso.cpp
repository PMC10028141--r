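// Graphical lasso by block coordinate descent (Friedman-Hastie-Tibshirani
// scheme): the covariance estimate W is updated one column at a time, each
// column update solving an L1-penalized quadratic program by coordinate
// descent.  The precision matrix is recovered from the converged W and the
// regression coefficients.  Warm starts across a descending lambda path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double t) {
  double a = std::abs(x) - t;
  return a > 0.0 ? (x > 0.0 ? a : -a) : 0.0;
}

// one lasso subproblem: min 0.5 b'W11 b - s12'b + lambda |b|_1
// beta updated in place; returns false on inner non-convergence.
// alternates full sweeps with cheap active-set sweeps over nonzeros.
static bool lasso_cd(const mat& W11, const vec& s12, double lambda,
                     double tol, int maxit, vec& beta) {
  const uword m = s12.n_elem;
  auto update = [&](uword k) {
    double grad = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
    double bnew = soft(grad, lambda) / W11(k, k);
    double del = std::abs(bnew - beta(k));
    beta(k) = bnew;
    return del;
  };
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (uword k = 0; k < m; ++k) maxdel = std::max(maxdel, update(k));
    if (maxdel < tol) return true;
    // active-set refinement between full sweeps
    for (int in = 0; in < maxit; ++in) {
      double d2 = 0.0;
      for (uword k = 0; k < m; ++k)
        if (beta(k) != 0.0) d2 = std::max(d2, update(k));
      if (d2 < tol) break;
    }
  }
  return false;
}

// full glasso at one lambda with warm-started W and B (p-1 x p betas).
// returns iterations used, or -1 on non-convergence
static int glasso_one(const mat& S, double lambda, double tol, int maxit,
                      bool pen_diag, mat& W, mat& B) {
  const uword p = S.n_rows;
  W.diag() = S.diag() + (pen_diag ? lambda : 0.0);
  if (p == 1) return 0;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      if (!lasso_cd(W11, s12, lambda, tol * 0.1, maxit, beta)) return -1;
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double del = std::abs(W(idx(k), j) - w12(k));
        if (del > maxdiff) maxdiff = del;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (maxdiff < tol) return it + 1;
  }
  return -1;
}

static mat recover_theta(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  if (p == 1) { Theta(0, 0) = 1.0 / W(0, 0); return Theta; }
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double tjj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    for (uword k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, double tol,
                     int maxit, bool penalize_diagonal) {
  mat W = S;
  mat B(S.n_rows > 1 ? S.n_rows - 1 : 1, S.n_rows, fill::zeros);
  int iters = glasso_one(S, lambda, tol, maxit, penalize_diagonal, W, B);
  mat Theta = recover_theta(W, B);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = iters >= 0);
}

// [[Rcpp::export(name = ".glasso_path_cd")]]
Rcpp::List glasso_path_cd(const arma::mat& S, const arma::vec& lambdas,
                          double tol, int maxit, bool penalize_diagonal) {
  const uword p = S.n_rows, L = lambdas.n_elem;
  cube thetas(p, p, L);
  ivec iters(L);
  mat W = S;
  mat B(p > 1 ? p - 1 : 1, p, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    int it = glasso_one(S, lambdas(l), tol, maxit, penalize_diagonal, W, B);
    iters(l) = it;
    thetas.slice(l) = recover_theta(W, B);
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("iterations") = iters);
}
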