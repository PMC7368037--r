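// Rank-1 L1-penalised decomposition of a cross-product matrix: the inner
// loop of the sparse CCA solver.  Mirrors the exported R operations
// soft_threshold() / l1_constrained_unit_vector(): alternating
// soft-thresholded unit-vector updates with the threshold found by
// bisection, initialised from the leading right singular vector.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// unit-L2 vector proportional to soft_threshold(a, delta) with the smallest
// delta >= 0 such that the L1 norm is <= c (bisection to tolerance `tol`)
static vec l1_unit(const vec &a, double c, double tol) {
  vec aa = abs(a);
  double l2 = norm(a, 2);
  if (l2 == 0.0) return a; // degenerate input: caller handles zero vectors
  if (accu(aa) <= c * l2 + tol) return a / l2;
  double lo = 0.0, hi = aa.max();
  for (int it = 0; it < 200; ++it) {
    double mid = (lo + hi) / 2.0;
    vec s = clamp(aa - mid, 0.0, datum::inf);
    double ss = norm(s, 2);
    if (ss == 0.0) {
      hi = mid;
    } else if (accu(s) > c * ss) {
      lo = mid;
    } else {
      hi = mid;
    }
    if (hi - lo <= tol * std::max(1.0, hi)) break;
  }
  vec s = clamp(aa - hi, 0.0, datum::inf);
  double ss = norm(s, 2);
  if (ss == 0.0) {
    // c >= 1 is always attainable with a single nonzero coordinate
    uword top = aa.index_max();
    vec w(a.n_elem, fill::zeros);
    w(top) = (a(top) >= 0.0) ? 1.0 : -1.0;
    return w;
  }
  return (sign(a) % s) / ss;
}

// [[Rcpp::export]]
Rcpp::List scca_rank1_cpp(const arma::mat &M, double cx, double cy,
                          double tol, int max_iter) {
  mat U, V;
  vec sv;
  svd_econ(U, sv, V, M);
  vec v = V.col(0);
  vec u(M.n_rows, fill::zeros);
  std::vector<double> obj;
  obj.reserve(16);
  bool converged = false;
  int iterations = 0;
  for (int it = 1; it <= max_iter; ++it) {
    iterations = it;
    vec u_new = l1_unit(M * v, cx, 1e-8);
    vec v_new = l1_unit(M.t() * u_new, cy, 1e-8);
    double delta = std::max(abs(u_new - u).max(), abs(v_new - v).max());
    u = u_new;
    v = v_new;
    obj.push_back(dot(u, M * v));
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  // orientation: largest-|weight| entry of v positive
  uword top = index_max(abs(v));
  if (v(top) < 0.0) {
    u = -u;
    v = -v;
  }
  double d = dot(u, M * v);
  return Rcpp::List::create(
      Rcpp::Named("u") = Rcpp::NumericVector(u.begin(), u.end()),
      Rcpp::Named("v") = Rcpp::NumericVector(v.begin(), v.end()),
      Rcpp::Named("d") = d, Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iterations,
      Rcpp::Named("objective") = Rcpp::NumericVector(obj.begin(), obj.end()));
}
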