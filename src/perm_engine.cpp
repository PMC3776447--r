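#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// type-7 (linear interpolation) percentile, prob in [0,1]
static double pct_type7(vec v, double prob) {
  v = sort(v);
  const uword m = v.n_elem;
  if (m == 1) return v[0];
  double h = (double)(m - 1) * prob;
  uword lo = (uword)std::floor(h);
  if (lo >= m - 1) return v[m - 1];
  return v[lo] + (h - (double)lo) * (v[lo + 1] - v[lo]);
}

// Quadratic score statistic Q = || V^{-1} Yc' xc ||^2 for each column of X,
// with the working covariance V re-estimated from the residuals of the
// per-gene regressions of Y on that column's x (as the permutation null
// requires: V is conditional on x).
//
// Yc: n x p column-centered expression; X: n x m phenotype columns
// kind: 1 = ridge unstructured, 2 = compound symmetry, 3 = fixed-k factor,
//       4 = adaptive factor
// Columns whose estimation or solve fails are returned as NaN; the R caller
// decides whether to retry or error.
// [[Rcpp::export]]
arma::vec perm_engine_cpp(const arma::mat& Yc, const arma::mat& X, int kind,
                          double ridge_prob, int n_factors,
                          double variance_fraction, int max_factors) {
  const uword n = Yc.n_rows, p = Yc.n_cols, m = X.n_cols;
  vec out(m);
  out.fill(datum::nan);

  for (uword b = 0; b < m; ++b) {
    vec x = X.col(b);
    vec xc = x - mean(x);
    double sxx = dot(xc, xc);
    if (!(sxx > 0)) continue;

    vec t = Yc.t() * xc;                      // sum_i (x_i - xbar) Y_i
    mat E = Yc - xc * (t / sxx).t();          // per-gene OLS residuals
    mat S = (E.t() * E) / double(n - 1);
    vec d = S.diag();
    double c5 = pct_type7(d, ridge_prob);
    if (!(max(d) > 0)) continue;              // no residual variability

    mat V;
    if (kind == 1) {                          // ridge unstructured
      V = S;
      V.diag() += c5;
    } else if (kind == 2) {                   // compound symmetry of the ridge
      mat Vr = S;
      Vr.diag() += c5;
      double dm = mean(Vr.diag());
      double om = p > 1 ? (accu(Vr) - trace(Vr)) / double(p * (p - 1)) : 0.0;
      V.set_size(p, p);
      V.fill(om);
      V.diag().fill(dm);
    } else {                                  // factor analysis of the ridge
      mat Vr = S;
      Vr.diag() += c5;
      vec eval;
      mat evec;
      if (!eig_sym(eval, evec, Vr)) continue; // ascending eigenvalues
      int k;
      if (kind == 3) {
        k = n_factors;
      } else {
        double tot = accu(eval), cum = 0.0;
        k = 0;
        for (uword j = p; j > 0; --j) {
          cum += eval[j - 1];
          ++k;
          if (cum / tot >= variance_fraction) break;
        }
        if (k > max_factors) k = max_factors;
      }
      if (k < 1 || (uword)k > p) continue;
      mat Uk = evec.cols(p - (uword)k, p - 1);
      vec lk = eval.subvec(p - (uword)k, p - 1);
      mat low = Uk * diagmat(lk) * Uk.t();
      vec D = Vr.diag() - low.diag();
      double fl = 1e-8 * mean(Vr.diag());
      D = clamp(D, fl, datum::inf);
      V = low;
      V.diag() = low.diag() + D;
    }

    vec U;
    bool ok = solve(U, V, t, solve_opts::no_approx + solve_opts::likely_sympd);
    if (!ok) continue;
    out[b] = dot(U, U);
  }
  return out;
}
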