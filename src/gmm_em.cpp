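// EM for diagonal-family Gaussian mixtures (structures EII, VII, EEI,
// VEI, EVI, VVI). The loop lives in C++ because model selection fits the
// full K x structure grid, often to the iteration cap, on every call.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// structure codes: 0 EII, 1 VII, 2 EEI, 3 VEI, 4 EVI, 5 VVI
static mat mstep_variances(const mat& W, const rowvec& nk, int code) {
  const uword K = W.n_rows, d = W.n_cols;
  const double n = accu(nk);
  mat V(K, d);
  switch (code) {
  case 0: V.fill(accu(W) / (n * d)); break;
  case 1: { vec s = sum(W, 1) / (conv_to<vec>::from(nk) * d);
            V = repmat(s, 1, d); } break;
  case 2: V = repmat(sum(W, 0) / n, K, 1); break;
  case 5: V = W; V.each_col() /= conv_to<vec>::from(nk).clamp(1e-300, datum::inf);
          break;
  case 4: { // equal volume, varying shape
    mat A(K, d);
    for (uword k = 0; k < K; ++k) {
      rowvec w = clamp(W.row(k), 1e-300, datum::inf);
      A.row(k) = w / std::exp(accu(log(w)) / d);
    }
    double lambda = accu(W / A) / (n * d);
    V = lambda * A;
  } break;
  case 3: { // varying volume, equal shape
    rowvec a = clamp(sum(W, 0) / n, 1e-300, datum::inf);
    a /= std::exp(accu(log(a)) / d);
    vec lambda(K, fill::ones);
    for (int it = 0; it < 10; ++it) {
      for (uword k = 0; k < K; ++k)
        lambda(k) = accu(W.row(k) / a) / (nk(k) * d);
      rowvec b(d, fill::zeros);
      for (uword k = 0; k < K; ++k)
        b += W.row(k) / std::max(lambda(k), 1e-300);
      a = clamp(b, 1e-300, datum::inf);
      a /= std::exp(accu(log(a)) / d);
    }
    V = lambda * a;
  } break;
  }
  return V;
}

// [[Rcpp::export]]
Rcpp::List gmm_em_cpp(const arma::mat& x, arma::mat Z, int code,
                      int max_iter, double tol) {
  const uword n = x.n_rows, d = x.n_cols, K = Z.n_cols;
  const mat x2 = square(x);
  std::vector<double> trace;
  trace.reserve(max_iter);
  mat means(K, d), V(K, d), post;
  rowvec weights(K);
  double ll_old = -datum::inf;
  bool ok = true, converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    rowvec nk = sum(Z, 0);
    if (nk.min() < 1e-10) { ok = false; break; }
    weights = nk / double(n);
    mat Zx = Z.t() * x;          // K x d
    means = Zx;
    means.each_col() /= conv_to<vec>::from(nk);
    mat m2 = square(means);
    m2.each_col() %= conv_to<vec>::from(nk);
    mat W = Z.t() * x2 - 2.0 * means % Zx + m2;
    W.clamp(0.0, datum::inf);
    V = mstep_variances(W, nk, code);
    if (!V.is_finite() || V.min() < 1e-12) { ok = false; break; }
    // E step: log densities via matrix products
    mat A = 1.0 / (2.0 * V);
    rowvec cst = log(weights) - 0.5 * sum(log(2.0 * datum::pi * V), 1).t()
                 - sum(A % square(means), 1).t();
    mat L = x * (2.0 * A % means).t() - x2 * A.t();
    L.each_row() += cst;
    vec mx = max(L, 1);
    mat P = exp(L.each_col() - mx);
    vec rs = sum(P, 1);
    post = P.each_col() / rs;
    double ll = accu(log(rs) + mx);
    trace.push_back(ll);
    Z = post;
    size_t m = trace.size();
    if (std::isfinite(ll_old) &&
        std::fabs(ll - ll_old) < tol * (1.0 + std::fabs(ll_old))) {
      converged = true; ll_old = ll; break;
    }
    if (m >= 3) {  // Aitken projection of the geometric tail
      double d1 = trace[m - 2] - trace[m - 3];
      double d2 = trace[m - 1] - trace[m - 2];
      if (d1 > 0 && d2 > 0 && d2 < d1) {
        double ll_inf = trace[m - 2] + d2 / (1.0 - d2 / d1);
        if (std::fabs(ll_inf - ll) < tol * (1.0 + std::fabs(ll))) {
          converged = true; ll_old = ll; break;
        }
      }
    }
    ll_old = ll;
  }
  return Rcpp::List::create(
    Rcpp::Named("ok") = ok,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("weights") = weights,
    Rcpp::Named("means") = means,
    Rcpp::Named("variances") = V,
    Rcpp::Named("loglik") = ll_old,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("posterior") = post);
}
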