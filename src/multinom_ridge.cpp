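// Ridge-penalized multinomial (softmax) logistic regression by damped Newton.
// Small dense problems only: this backs the cross-validated deviance criterion
// of sequential forward selection, which performs tens of thousands of tiny
// fits (n ~ 100, p <= ~25, K = 5).
//
// Model: P(y = k | x) = softmax(x' B_k); full K-column parametrization made
// identifiable by the ridge penalty, which is applied to all coefficients
// including the intercept row (lambda is small; the bias it introduces is
// negligible against class-balanced data).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double objective(const mat& X, const uvec& y, const mat& B,
                        double lambda, mat& P) {
  mat eta = X * B;
  vec m = max(eta, 1);
  eta.each_col() -= m;
  P = exp(eta);
  vec denom = sum(P, 1);
  P.each_col() /= denom;
  double nll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double p = std::max(P(i, y(i)), 1e-300);
    nll -= std::log(p);
  }
  return nll + 0.5 * lambda * accu(B % B);
}

// [[Rcpp::export]]
Rcpp::List multinom_ridge_fit(const arma::mat& X, const arma::uvec& y,
                              int K, double lambda, int maxit = 50,
                              double tol = 1e-9) {
  const uword n = X.n_rows, p = X.n_cols;
  mat B(p, K, fill::zeros);
  mat P;
  double obj = objective(X, y, B, lambda, P);

  mat Y(n, K, fill::zeros);
  for (uword i = 0; i < n; ++i) Y(i, y(i)) = 1.0;

  int it = 0;
  for (; it < maxit; ++it) {
    mat G = X.t() * (P - Y) + lambda * B;           // p x K
    double gnorm = norm(vectorise(G), 2);
    if (gnorm < tol * (1.0 + std::abs(obj))) break;

    // Full Hessian of size (pK) x (pK): blocks H_{kl} = X' W_{kl} X + lambda I d_{kl}
    mat H(p * K, p * K, fill::zeros);
    for (int k = 0; k < K; ++k) {
      for (int l = k; l < K; ++l) {
        vec w;
        if (k == l) w = P.col(k) % (1.0 - P.col(k));
        else        w = -P.col(k) % P.col(l);
        mat blk = X.t() * (X.each_col() % w);
        if (k == l) blk.diag() += lambda;
        H.submat(k * p, l * p, k * p + p - 1, l * p + p - 1) = blk;
        if (l != k)
          H.submat(l * p, k * p, l * p + p - 1, k * p + p - 1) = blk.t();
      }
    }
    vec step;
    bool ok = solve(step, H, -vectorise(G), solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-6;
      step = solve(H, -vectorise(G));
    }

    // Backtracking line search on the penalized deviance.
    double t = 1.0;
    mat Bnew, Pnew;
    double objnew = obj;
    bool accepted = false;
    for (int ls = 0; ls < 30; ++ls) {
      Bnew = B + t * reshape(step, p, K);
      objnew = objective(X, y, Bnew, lambda, Pnew);
      if (objnew <= obj - 1e-12) { accepted = true; break; }
      t *= 0.5;
    }
    if (!accepted) break;
    double drop = obj - objnew;
    B = Bnew; P = Pnew; obj = objnew;
    if (drop < tol * (1.0 + std::abs(obj))) { ++it; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("coef") = B,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("iterations") = it
  );
}

// [[Rcpp::export]]
arma::mat multinom_ridge_prob(const arma::mat& X, const arma::mat& B) {
  mat eta = X * B;
  vec m = max(eta, 1);
  eta.each_col() -= m;
  mat P = exp(eta);
  vec denom = sum(P, 1);
  P.each_col() /= denom;
  return P;
}
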