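// Sliding-window VIF pruning. Dosages arrive mean-imputed; columns are
// standardized here so each window's Gram matrix is a correlation matrix and
// VIF_j is the j-th diagonal of its inverse. Removals are global and the
// sweep repeats up to `passes` times over the surviving list.
//
// Correlations between variants fewer than `window` positions apart are
// precomputed once as a band; windows whose members span wider (possible
// only after removals in earlier passes) fall back to a direct Gram product.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// VIFs for one window from its correlation matrix. Rank-deficient windows
// (duplicate/collinear variants) fall back to pseudoinverse R^2 per column.
static vec gram_vif(const mat& C) {
  const uword w = C.n_rows;
  mat inv;
  if (inv_sympd(inv, C)) {
    vec v = inv.diag();
    if (v.min() > 1.0 - 1e-8) return clamp(v, 1.0, datum::inf);
  }
  vec v(w);
  for (uword j = 0; j < w; ++j) {
    uvec others(w - 1);
    uword t = 0;
    for (uword i = 0; i < w; ++i) if (i != j) others[t++] = i;
    mat Cm = C.submat(others, others);
    vec g = C.col(j);
    g = g.elem(others);
    vec b = pinv(Cm) * g;
    double r2 = dot(g, b);
    if (r2 >= 1.0 - 1e-12) v[j] = datum::inf;
    else v[j] = std::max(1.0 / (1.0 - r2), 1.0);
  }
  return v;
}

// [[Rcpp::export]]
Rcpp::LogicalVector ld_prune_cpp(arma::mat& D, const arma::vec& maf,
                                 int window, int step, double vif_max,
                                 int passes) {
  const uword n = D.n_rows, m = D.n_cols;
  const double denom = static_cast<double>(n) - 1.0;
  // standardize columns in place; zero-variance columns become all-zero
  for (uword j = 0; j < m; ++j) {
    double mu = mean(D.col(j));
    double s = stddev(D.col(j));
    if (s > 1e-12) D.col(j) = (D.col(j) - mu) / s;
    else D.col(j).zeros();
  }
  // banded correlations: band(j, k) = cor(variant j, variant j + k + 1)
  const uword bw = static_cast<uword>(window) - 1;
  mat band(m, bw, fill::zeros);
  for (uword j = 0; j + 1 < m; ++j) {
    uword hi = std::min(j + bw, m - 1);
    vec r = D.cols(j + 1, hi).t() * D.col(j) / denom;
    band.row(j).cols(0, hi - j - 1) = r.t();
  }
  auto band_cor = [&](uword a, uword b) -> double {
    if (a == b) return 1.0;
    uword lo = std::min(a, b), hi = std::max(a, b);
    return band(lo, hi - lo - 1);
  };

  std::vector<bool> keep(m, true);
  for (int pass = 0; pass < passes; ++pass) {
    bool removed_this_pass = false;
    std::vector<uword> cur;
    cur.reserve(m);
    for (uword j = 0; j < m; ++j) if (keep[j]) cur.push_back(j);
    if (cur.size() < 2) break;
    for (size_t s0 = 0; s0 < cur.size(); s0 += step) {
      size_t s1 = std::min(s0 + static_cast<size_t>(window), cur.size());
      std::vector<uword> win;
      for (size_t i = s0; i < s1; ++i) if (keep[cur[i]]) win.push_back(cur[i]);
      while (win.size() >= 2) {
        const uword w = win.size();
        mat C(w, w);
        if (win.back() - win.front() <= bw) {
          for (uword a = 0; a < w; ++a) {
            C(a, a) = 1.0;
            for (uword b = a + 1; b < w; ++b) {
              double r = band_cor(win[a], win[b]);
              C(a, b) = r;
              C(b, a) = r;
            }
          }
        } else {
          uvec idx(w);
          for (uword i = 0; i < w; ++i) idx[i] = win[i];
          mat Zw = D.cols(idx);
          C = (Zw.t() * Zw) / denom;
          C.diag().ones();
        }
        vec v = gram_vif(C);
        double vmax = v.max();
        if (vmax < vif_max) break;
        // ties on the max VIF: remove lower MAF, then lower panel index
        uword worst = 0;
        bool found = false;
        for (uword i = 0; i < v.n_elem; ++i) {
          bool is_max = std::isinf(vmax) ? std::isinf(v[i])
                                         : (v[i] >= vmax * (1.0 - 1e-8));
          if (!is_max) continue;
          if (!found || maf[win[i]] < maf[win[worst]] - 1e-15 ||
              (std::abs(maf[win[i]] - maf[win[worst]]) <= 1e-15 && win[i] < win[worst])) {
            worst = i;
            found = true;
          }
        }
        keep[win[worst]] = false;
        removed_this_pass = true;
        win.erase(win.begin() + worst);
      }
    }
    if (!removed_this_pass) break;
  }
  Rcpp::LogicalVector out(m);
  for (uword j = 0; j < m; ++j) out[j] = keep[j];
  return out;
}
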