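#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Pointwise (1x1) convolution as a BLAS matrix product over all pixels of a
// (C, H, W, B) tensor viewed as C x (H*W*B), without copying the input.

// [[Rcpp::export]]
Rcpp::NumericVector cpp_pw_fwd(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                               int C) {
  arma::mat X(x.begin(), C, x.size() / C, false, true);
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false, true);
  Rcpp::NumericVector out((R_xlen_t)w.nrow() * (x.size() / C));
  arma::mat Y(out.begin(), w.nrow(), x.size() / C, false, true);
  Y = W * X;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_pw_bwd(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                      Rcpp::NumericVector dy, int C) {
  R_xlen_t m = x.size() / C;
  arma::mat X(x.begin(), C, m, false, true);
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::mat G(dy.begin(), w.nrow(), m, false, true);
  Rcpp::NumericVector dxv(x.size());
  arma::mat DX(dxv.begin(), C, m, false, true);
  DX = W.t() * G;
  Rcpp::NumericMatrix dwv(w.nrow(), w.ncol());
  arma::mat DW(dwv.begin(), w.nrow(), w.ncol(), false, true);
  DW = G * X.t();
  return Rcpp::List::create(Rcpp::_["dx"] = dxv, Rcpp::_["dw"] = dwv);
}
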