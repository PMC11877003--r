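// Batched LSTM forward/backward. Cubes are (batch x feature x time): slice t
// holds the B x D matrix of time step t. Gate order: i, f, o, g.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sig(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".lstm_fwd_cpp")]]
Rcpp::List lstm_fwd_cpp(const arma::mat& W, const arma::mat& U,
                        const arma::vec& b, const arma::cube& X) {
  const uword B = X.n_rows, Tn = X.n_slices, H = U.n_rows;
  cube Hc(B, H, Tn), Ic(B, H, Tn), Fc(B, H, Tn), Oc(B, H, Tn), Gc(B, H, Tn),
      Cc(B, H, Tn);
  mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < Tn; ++t) {
    mat Z = X.slice(t) * W + h_prev * U;
    Z.each_row() += br;
    mat i = sig(Z.cols(0, H - 1));
    mat f = sig(Z.cols(H, 2 * H - 1));
    mat o = sig(Z.cols(2 * H, 3 * H - 1));
    mat g = tanh(Z.cols(3 * H, 4 * H - 1));
    mat c_t = f % c_prev + i % g;
    mat h_t = o % tanh(c_t);
    Ic.slice(t) = i; Fc.slice(t) = f; Oc.slice(t) = o; Gc.slice(t) = g;
    Cc.slice(t) = c_t; Hc.slice(t) = h_t;
    h_prev = h_t; c_prev = c_t;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = Hc, Rcpp::Named("i") = Ic, Rcpp::Named("f") = Fc,
      Rcpp::Named("o") = Oc, Rcpp::Named("g") = Gc, Rcpp::Named("c") = Cc);
}

// [[Rcpp::export(name = ".lstm_bwd_cpp")]]
Rcpp::List lstm_bwd_cpp(const arma::mat& W, const arma::mat& U,
                        const arma::cube& X, const arma::cube& Hc,
                        const arma::cube& Ic, const arma::cube& Fc,
                        const arma::cube& Oc, const arma::cube& Gc,
                        const arma::cube& Cc, const arma::cube& dH) {
  const uword B = X.n_rows, D = X.n_cols, Tn = X.n_slices, H = U.n_rows;
  mat dW(D, 4 * H, fill::zeros), dU(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  cube dX(B, D, Tn);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword tt = Tn; tt-- > 0;) {
    const mat& i = Ic.slice(tt); const mat& f = Fc.slice(tt);
    const mat& o = Oc.slice(tt); const mat& g = Gc.slice(tt);
    const mat& c_t = Cc.slice(tt);
    mat c_prev = (tt > 0) ? Cc.slice(tt - 1) : mat(B, H, fill::zeros);
    mat h_prev = (tt > 0) ? Hc.slice(tt - 1) : mat(B, H, fill::zeros);
    mat tc = tanh(c_t);
    mat dh = dH.slice(tt) + dh_next;
    mat dc = dc_next + dh % o % (1 - tc % tc);
    mat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = (dc % g) % i % (1 - i);
    dZ.cols(H, 2 * H - 1) = (dc % c_prev) % f % (1 - f);
    dZ.cols(2 * H, 3 * H - 1) = (dh % tc) % o % (1 - o);
    dZ.cols(3 * H, 4 * H - 1) = (dc % i) % (1 - g % g);
    dW += X.slice(tt).t() * dZ;
    dU += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dX.slice(tt) = dZ * W.t();
    dh_next = dZ * U.t();
    dc_next = dc % f;
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("dU") = dU,
                            Rcpp::Named("db") = db.t(),
                            Rcpp::Named("dX") = dX);
}
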