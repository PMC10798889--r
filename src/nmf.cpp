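// Multiplicative-update NMF minimizing generalized Kullback-Leibler
// divergence (the classic consensus-clustering NMF setup), with a Frobenius
// variant behind a flag. Initial factors are drawn in R so that runs are
// reproducible from the R RNG seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_objective(const mat& X, const mat& WH) {
  const double eps = 1e-12;
  // sum over entries of x*log(x/y) - x + y, with the x = 0 limit = y
  mat term = WH - X;
  uvec nz = find(X > 0);
  vec xv = X.elem(nz);
  vec yv = WH.elem(nz);
  return accu(term) + accu(xv % log(xv / (yv + eps)));
}

// [[Rcpp::export(name = ".nmf_run")]]
Rcpp::List nmf_run(const arma::mat& X, arma::mat W, arma::mat H,
                   int max_iter, double tol, int check_every,
                   bool frobenius) {
  const double eps = 1e-12;
  mat WH = W * H;
  double obj = frobenius ? accu(square(X - WH)) : kl_objective(X, WH);
  std::vector<double> trace;
  trace.push_back(obj);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    if (frobenius) {
      H %= (W.t() * X) / (W.t() * WH + eps);
      WH = W * H;
      W %= (X * H.t()) / (WH * H.t() + eps);
    } else {
      // KL updates: H <- H .* (W' (X ./ WH)) ./ (W' 1)
      mat R = X / (WH + eps);
      H %= (W.t() * R);
      H.each_col() /= (sum(W, 0).t() + eps);
      WH = W * H;
      R = X / (WH + eps);
      W %= (R * H.t());
      W.each_row() /= (sum(H, 1).t() + eps);
    }
    WH = W * H;
    if (it % check_every == 0 || it == max_iter) {
      double newobj = frobenius ? accu(square(X - WH)) : kl_objective(X, WH);
      trace.push_back(newobj);
      double rel = std::fabs(obj - newobj) / std::max(1.0, std::fabs(obj));
      obj = newobj;
      if (rel < tol) { converged = true; break; }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = std::min(it, max_iter));
}
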