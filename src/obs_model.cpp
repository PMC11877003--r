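// Observation-model likelihood and gradients.
//
// The model evaluates, for every time point t of a flattened batch,
//   x_t ~ N(0, C_t)
// where either
//   C_t = G_t F_t G_t,  G_t = diag(alpha_t %*% e),  F_t = sum_j beta_jt R_j
// (multi-dynamic: separate power and FC mixtures) or
//   C_t = sum_j alpha_jt C_j
// (single-dynamic: one mixture of full covariances).
//
// Gradients are returned with respect to the mixing weights and the mode
// matrices; chaining into the unconstrained parameterisations (softplus for
// the E diagonals, normalised Cholesky factors for the R_j) is done in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Cholesky with an informative error carrying the (1-based) time index.
static mat chol_or_stop(const mat& C, unsigned int t) {
  mat L;
  if (!chol(L, C, "lower")) {
    Rcpp::stop("covariance at time index %d is not positive definite (Cholesky failed)",
               t + 1);
  }
  return L;
}

// [[Rcpp::export(name = ".obs_gfg_cpp")]]
Rcpp::List obs_gfg_cpp(const arma::mat& X,      // N x Nc data
                       const arma::mat& A,      // N x J1 power mixing (simplex rows)
                       const arma::mat& B,      // N x J2 FC mixing
                       const arma::mat& e,      // J1 x Nc diagonals of E_j
                       const arma::cube& R,     // Nc x Nc x J2 correlation modes
                       const bool grad) {
  const uword N = X.n_rows, Nc = X.n_cols, J1 = A.n_cols, J2 = B.n_cols;
  vec ll(N);
  mat dA, dB, de;
  cube dR;
  if (grad) {
    dA.zeros(N, J1);
    dB.zeros(N, J2);
    de.zeros(J1, Nc);
    dR.zeros(Nc, Nc, J2);
  }
  for (uword t = 0; t < N; ++t) {
    rowvec g = A.row(t) * e;                     // per-channel std devs
    mat F(Nc, Nc, fill::zeros);
    for (uword j = 0; j < J2; ++j) F += B(t, j) * R.slice(j);
    mat C = F;
    C.each_row() %= g;
    C.each_col() %= g.t();
    mat L = chol_or_stop(C, t);
    vec x = X.row(t).t();
    vec z = solve(trimatl(L), x);
    ll(t) = -0.5 * Nc * LOG2PI - accu(log(L.diag())) - 0.5 * dot(z, z);
    if (grad) {
      mat Cinv = inv_sympd(C);
      vec w = Cinv * x;
      mat S = -0.5 * (Cinv - w * w.t());         // d ll / d C, entries independent
      vec dg = 2.0 * ((S % F) * g.t());
      mat dF = S % (g.t() * g);
      for (uword j = 0; j < J2; ++j) {
        dB(t, j) = accu(dF % R.slice(j));
        dR.slice(j) += B(t, j) * dF;
      }
      dA.row(t) = (e * dg).t();
      de += A.row(t).t() * dg.t();
    }
  }
  if (!grad) return Rcpp::List::create(Rcpp::Named("ll") = ll);
  return Rcpp::List::create(Rcpp::Named("ll") = ll, Rcpp::Named("dA") = dA,
                            Rcpp::Named("dB") = dB, Rcpp::Named("de") = de,
                            Rcpp::Named("dR") = dR);
}

// Per-time-point covariances (no mixture): ll_t = log N(x_t | 0, C[,,t]).
// [[Rcpp::export(name = ".loglik_tv_cpp")]]
arma::vec loglik_tv_cpp(const arma::mat& X, const arma::cube& C) {
  const uword N = X.n_rows, Nc = X.n_cols;
  if (C.n_slices != N) Rcpp::stop("covariance count does not match sample count");
  vec ll(N);
  for (uword t = 0; t < N; ++t) {
    mat L = chol_or_stop(C.slice(t), t);
    vec z = solve(trimatl(L), X.row(t).t());
    ll(t) = -0.5 * Nc * LOG2PI - accu(log(L.diag())) - 0.5 * dot(z, z);
  }
  return ll;
}

// [[Rcpp::export(name = ".obs_full_cpp")]]
Rcpp::List obs_full_cpp(const arma::mat& X,     // N x Nc
                        const arma::mat& A,     // N x J
                        const arma::cube& Cj,   // Nc x Nc x J covariance modes
                        const bool grad) {
  const uword N = X.n_rows, Nc = X.n_cols, J = A.n_cols;
  vec ll(N);
  mat dA;
  cube dC;
  if (grad) {
    dA.zeros(N, J);
    dC.zeros(Nc, Nc, J);
  }
  for (uword t = 0; t < N; ++t) {
    mat C(Nc, Nc, fill::zeros);
    for (uword j = 0; j < J; ++j) C += A(t, j) * Cj.slice(j);
    mat L = chol_or_stop(C, t);
    vec x = X.row(t).t();
    vec z = solve(trimatl(L), x);
    ll(t) = -0.5 * Nc * LOG2PI - accu(log(L.diag())) - 0.5 * dot(z, z);
    if (grad) {
      mat Cinv = inv_sympd(C);
      vec w = Cinv * x;
      mat S = -0.5 * (Cinv - w * w.t());
      for (uword j = 0; j < J; ++j) {
        dA(t, j) = accu(S % Cj.slice(j));
        dC.slice(j) += A(t, j) * S;
      }
    }
  }
  if (!grad) return Rcpp::List::create(Rcpp::Named("ll") = ll);
  return Rcpp::List::create(Rcpp::Named("ll") = ll, Rcpp::Named("dA") = dA,
                            Rcpp::Named("dC") = dC);
}
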