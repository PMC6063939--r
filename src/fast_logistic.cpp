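// Per-variant logistic regression scan (IRLS / Fisher scoring), the hot loop
// of the association stage. Each variant j is fit as
//   logit P(y=1) = [covariates, dosage_j] * beta
// with covariates shared across variants. Dosages arrive mean-imputed.
//
// Each scoring iteration is one fused pass over the observations: the linear
// predictor, mean, IRLS weight, log-likelihood, Fisher information and score
// vector are accumulated together, with no per-variant temporaries.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// at most this many columns in [covariates, dosage]
static const int kMaxP = 24;

// One Fisher-scoring pass at the current beta: fills the upper triangle of
// the Fisher information A (p x p, column-major in a flat buffer) and the
// score vector s. Design is [C, d]; d may be null (covariate-only model).
static void scoring_pass(const mat& C, const double* d, const vec& y,
                         const double* beta, int p, double* A, double* s) {
  const uword n = C.n_rows, c = C.n_cols;
  const double* cols[kMaxP];
  for (uword k = 0; k < c; ++k) cols[k] = C.colptr(k);
  const double* yp = y.memptr();
  double x[kMaxP];
  for (int a = 0; a < p * p; ++a) A[a] = 0.0;
  for (int a = 0; a < p; ++a) s[a] = 0.0;
  if (c == 1 && d) {
    // intercept + dosage, the common unadjusted scan: unrolled accumulators
    const double b0 = beta[0], b1 = beta[1];
    double s0 = 0, s1 = 0, a00 = 0, a01 = 0, a11 = 0;
    for (uword i = 0; i < n; ++i) {
      double di = d[i];
      double e = b0 + di * b1;
      double ex = std::exp(e >= 0 ? -e : e); // in (0, 1]
      double m = (e >= 0) ? 1.0 / (1.0 + ex) : ex / (1.0 + ex);
      m = std::min(std::max(m, 1e-10), 1.0 - 1e-10);
      double w = m * (1.0 - m);
      double r = yp[i] - m;
      s0 += r;
      s1 += r * di;
      a00 += w;
      a01 += w * di;
      a11 += w * di * di;
    }
    s[0] = s0; s[1] = s1;
    A[0] = a00; A[1] = a01; A[2] = a01; A[3] = a11;
    return;
  }
  for (uword i = 0; i < n; ++i) {
    double e = 0.0;
    for (uword k = 0; k < c; ++k) {
      x[k] = cols[k][i];
      e += x[k] * beta[k];
    }
    if (d) {
      x[c] = d[i];
      e += x[c] * beta[c];
    }
    double ex = std::exp(e >= 0 ? -e : e);
    double m = (e >= 0) ? 1.0 / (1.0 + ex) : ex / (1.0 + ex);
    m = std::min(std::max(m, 1e-10), 1.0 - 1e-10);
    double w = m * (1.0 - m);
    double r = yp[i] - m;
    for (int a = 0; a < p; ++a) {
      s[a] += r * x[a];
      double wxa = w * x[a];
      for (int b = a; b < p; ++b) A[a + b * p] += wxa * x[b];
    }
  }
  for (int a = 0; a < p; ++a)
    for (int b = 0; b < a; ++b) A[a + b * p] = A[b + a * p];
}

// IRLS with warm start. Convergence is judged by the Newton decrement
// s' A^{-1} s / 2, the second-order estimate of the remaining
// log-likelihood improvement, against `tol`; the converged beta then takes
// the final (vanishing) Newton step and cov is the inverse Fisher
// information at that point. Returns true on convergence.
static bool irls(const mat& C, const double* d, const vec& y, vec& beta,
                 mat& cov, int max_iter, double tol, double beta_cap,
                 bool& separated) {
  separated = false;
  const int p = beta.n_elem;
  if (p > kMaxP) Rcpp::stop("too many covariates (max %d).", kMaxP - 1);
  double Abuf[kMaxP * kMaxP], sbuf[kMaxP];
  for (int it = 0; it <= max_iter; ++it) {
    scoring_pass(C, d, y, beta.memptr(), p, Abuf, sbuf);
    mat A(Abuf, p, p, false, true);
    vec sv(sbuf, p, false, true);
    vec delta;
    if (!solve(delta, A, sv, solve_opts::no_approx)) return false;
    double decrement = 0.5 * dot(sv, delta);
    beta += delta;
    if (abs(beta).max() > beta_cap) {
      separated = true;
      return false;
    }
    if (std::abs(decrement) < tol) {
      // one more pass for the information matrix at the final beta
      scoring_pass(C, d, y, beta.memptr(), p, Abuf, sbuf);
      mat A2(Abuf, p, p, false, true);
      bool ok = inv_sympd(cov, A2);
      if (!ok) ok = inv(cov, A2);
      return ok;
    }
  }
  return false;
}

// [[Rcpp::export]]
Rcpp::List logistic_scan_cpp(const arma::mat& C, const arma::mat& D,
                             const arma::vec& y, int max_iter = 25,
                             double tol = 1e-8, double beta_cap = 25.0) {
  const uword c = C.n_cols, m = D.n_cols;
  vec beta0(c, fill::zeros);
  mat cov0(c, c);
  bool sep0;
  // null (covariate-only) fit provides warm starts for every variant
  bool null_ok = irls(C, nullptr, y, beta0, cov0, 50, tol, beta_cap, sep0);
  if (!null_ok) beta0.zeros();

  vec log_or(m, fill::value(datum::nan));
  vec se(m, fill::value(datum::nan));
  vec pval(m, fill::value(datum::nan));
  uvec converged(m, fill::zeros);
  uvec zero_var(m, fill::zeros);

  for (uword j = 0; j < m; ++j) {
    const double* d = D.colptr(j);
    double v = var(D.col(j));
    if (!std::isfinite(v) || v < 1e-12) {
      zero_var[j] = 1;
      continue;
    }
    vec beta(c + 1, fill::zeros);
    beta.head(c) = beta0;
    mat cov;
    bool sep;
    if (irls(C, d, y, beta, cov, max_iter, tol, beta_cap, sep)) {
      double b = beta[c];
      double s = std::sqrt(cov(c, c));
      log_or[j] = b;
      se[j] = s;
      double z2 = (b / s) * (b / s);
      pval[j] = R::pchisq(z2, 1.0, 0, 0);
      converged[j] = 1;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("log_or") = log_or, Rcpp::Named("se") = se,
      Rcpp::Named("p") = pval, Rcpp::Named("converged") = converged,
      Rcpp::Named("zero_variance") = zero_var);
}

// Column-mean imputation of missing genotype calls, integer 0/1/2/NA in,
// double out.
// [[Rcpp::export]]
Rcpp::NumericMatrix impute_dosages_cpp(const Rcpp::IntegerMatrix& D) {
  const int n = D.nrow(), m = D.ncol();
  Rcpp::NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    double sum = 0.0;
    int nn = 0;
    for (int i = 0; i < n; ++i) {
      int g = D(i, j);
      if (g != NA_INTEGER) {
        sum += g;
        ++nn;
      }
    }
    double mu = nn > 0 ? sum / nn : 0.0;
    for (int i = 0; i < n; ++i) {
      int g = D(i, j);
      out(i, j) = (g == NA_INTEGER) ? mu : g;
    }
  }
  return out;
}

// Genotype counts per variant in one pass: n0, n1, n2, n_missing.
// [[Rcpp::export]]
Rcpp::IntegerMatrix geno_counts_cpp(const Rcpp::IntegerMatrix& D) {
  const int n = D.nrow(), m = D.ncol();
  Rcpp::IntegerMatrix out(m, 4);
  for (int j = 0; j < m; ++j) {
    int c0 = 0, c1 = 0, c2 = 0, cm = 0;
    for (int i = 0; i < n; ++i) {
      int g = D(i, j);
      if (g == NA_INTEGER) ++cm;
      else if (g == 0) ++c0;
      else if (g == 1) ++c1;
      else ++c2;
    }
    out(j, 0) = c0;
    out(j, 1) = c1;
    out(j, 2) = c2;
    out(j, 3) = cm;
  }
  return out;
}
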