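// Graphical lasso: block coordinate descent over columns of the working
// covariance (Friedman-style), with warm starts along a lambda path.
// Returns the precision matrix per lambda.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso fit at fixed lambda, warm-started from W and B (beta matrix,
// column j holds the p-1 regression coefficients for column j).
static bool glasso_fit(const mat& S, double lambda, mat& W, mat& B,
                       int maxit, double tol) {
  const int p = S.n_rows;
  const double offmean = mean(mean(abs(S - diagmat(S.diag())))) + 1e-12;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // indices excluding j
      uvec idx(p - 1);
      int c = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      vec s12 = S.col(j); s12.shed_row(j);
      vec beta = B.col(j);
      // lasso coordinate descent on: 0.5 b'W11 b - b's12 + lambda|b|_1
      for (int inner = 0; inner < 1000; ++inner) {
        double dmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          const uword rk = idx(k);
          double wkk = W(rk, rk);
          // residual gradient excluding k
          double grad = s12(k);
          for (int l = 0; l < p - 1; ++l) {
            if (l == k) continue;
            grad -= W(rk, idx(l)) * beta(l);
          }
          double bnew = soft(grad, lambda) / wkk;
          double d = std::abs(bnew - beta(k));
          if (d > dmax) dmax = d;
          beta(k) = bnew;
        }
        if (dmax < tol * 1e-2) break;
      }
      B.col(j) = beta;
      vec w12 = W(idx, idx) * beta;
      for (int k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > delta) delta = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (delta < tol * offmean) return true;
  }
  return false;
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           int maxit = 200, double tol = 1e-6) {
  const int p = S.n_rows;
  const int L = lambdas.n_elem;
  mat W = S + lambdas(0) * eye(p, p);
  mat B(p - 1, p, fill::zeros);
  Rcpp::List thetas(L);
  Rcpp::LogicalVector converged(L);
  for (int m = 0; m < L; ++m) {
    double lambda = lambdas(m);
    // reset working diagonal for this lambda
    for (int j = 0; j < p; ++j) W(j, j) = S(j, j) + lambda;
    bool ok = glasso_fit(S, lambda, W, B, maxit, tol);
    converged[m] = ok;
    // recover Theta from W and B
    mat Theta(p, p, fill::zeros);
    for (int j = 0; j < p; ++j) {
      uvec idx(p - 1);
      int c = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      vec beta = B.col(j);
      vec w12 = W.col(j); w12.shed_row(j);
      double denom = W(j, j) - dot(w12, beta);
      double t22 = 1.0 / denom;
      Theta(j, j) = t22;
      for (int k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * t22;
    }
    Theta = 0.5 * (Theta + Theta.t());
    thetas[m] = Theta;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("converged") = converged);
}
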