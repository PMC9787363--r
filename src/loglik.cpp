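#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// lgamma(k + 1) lookup, grown on demand; single-threaded package so a
// static cache is safe.
static std::vector<double> lgam_tab;

static inline double lgam1(int k) {
  if (k < 0) return R_PosInf; // guards impossible pmf arguments
  if ((size_t)k >= lgam_tab.size()) {
    size_t old = lgam_tab.size();
    lgam_tab.resize(k + 1024);
    for (size_t i = old; i < lgam_tab.size(); ++i)
      lgam_tab[i] = std::lgamma((double)i + 1.0);
  }
  return lgam_tab[k];
}

// Terms with log-weight below the running maximum plus LOG_REL_TOL are
// outside the summation window; the marginal is insensitive to further
// widening at well below 1e-10.
static const double LOG_REL_TOL = std::log(1e-15);

struct CellCtx {
  int n, a, L;
  double D, r, lam, T, M;
  double logD, l1p, lp;   // l1p = log(1 - p_capture) = -rT
  double lamM;            // lam * M
  double lchooseLa;
};

// log term at N (joint pmf of N, n, a given parameters), with the
// lgamma(N+1) of the Poisson cancelled against the binomial coefficient.
static double log_term(const CellCtx &c, int N, double q /* exp(-lamM*N) */) {
  double lt = N * c.logD - c.D - lgam1(c.n) - lgam1(N - c.n)
            + (N - c.n) * c.l1p;
  if (c.n > 0) lt += c.n * c.lp;
  if (c.L > 0) {
    lt += c.lchooseLa + (c.L - c.a) * (-c.lamM * N);
    if (c.a > 0) lt += c.a * std::log1p(-q);
  }
  return lt;
}

// Marginal log-likelihood of (n, a) for one guild x event cell:
// log sum_{N >= n} Pois(N; D) Binom(n; N, 1-e^{-rT}) Binom(a; L, 1-e^{-lam N M}).
// Unimodal in N; summed over an adaptive window around the mode with
// streaming log-sum-exp.
static double cell_marginal(int n, int a, double D, double r, double lam,
                            int L, double T, double M, bool integrated) {
  // numerical guard: divergent proposals with astronomically large expected
  // abundance are rejected outright; far beyond any plausible population.
  if (D > 1e6) return R_NegInf;
  if (!integrated || L == 0) {
    // Poisson thinning: marginal of n is Poisson(D * p_capture)
    double p = -std::expm1(-r * T);
    double mu = D * p;
    double lmr;
    if (mu == 0.0) lmr = (n == 0) ? 0.0 : R_NegInf;
    else lmr = n * std::log(mu) - mu - lgam1(n);
    if (integrated && L == 0) return lmr; // no listening periods: a absent
    if (!integrated) return lmr;
  }

  if (a > L) return R_NegInf;

  CellCtx c;
  c.n = n; c.a = a; c.L = L; c.D = D; c.r = r; c.lam = lam; c.T = T; c.M = M;
  double p = -std::expm1(-r * T);
  if (D <= 0.0) {
    // degenerate latent population: N = 0 almost surely
    if (n > 0) return R_NegInf;
    return (a == 0) ? 0.0 : R_NegInf;
  }
  if (p <= 0.0 && n > 0) return R_NegInf;
  c.logD = std::log(D);
  c.l1p = -r * T;
  c.lp = (p > 0) ? std::log(p) : R_NegInf;
  c.lamM = lam * M;
  c.lchooseLa = (L > 0) ? (lgam1(L) - lgam1(a) - lgam1(L - a)) : 0.0;

  double qf = std::exp(-c.lamM); // per-unit-N acoustic survival factor

  int N = std::max(n, (int)D);
  double q = std::exp(-c.lamM * N);
  double lt = log_term(c, N, q);

  // climb to the mode
  long guard = 0;
  for (;;) {
    double qn = q * qf;
    double up = log_term(c, N + 1, qn);
    if (std::isnan(up)) break;
    if (up > lt) { N++; q = qn; lt = up; }
    else break;
    if (++guard > 10000000L) Rcpp::stop("latent-N mode search did not terminate");
  }
  for (;;) {
    if (N <= n) break;
    double qd = (qf > 0) ? q / qf : std::exp(-c.lamM * (N - 1));
    double dn = log_term(c, N - 1, qd);
    if (std::isnan(dn)) break;
    if (dn >= lt) { N--; q = qd; lt = dn; }
    else break;
    if (++guard > 10000000L) Rcpp::stop("latent-N mode search did not terminate");
  }

  int Nm = N;
  double ltm = lt, qm = q;
  if (!R_FINITE(ltm)) {
    // whole support negligible / impossible (e.g. a > 0 with lam = 0)
    // fall through: sum only finite contributions below
  }
  double s = R_FINITE(ltm) ? 1.0 : 0.0;

  // upward sweep
  q = qm;
  for (int Ni = Nm + 1;; ++Ni) {
    q *= qf;
    double lti = log_term(c, Ni, q);
    double rel = lti - ltm;
    if (std::isnan(rel) || rel < LOG_REL_TOL) break;
    s += std::exp(rel);
    if (++guard > 10000000L) Rcpp::stop("latent-N summation did not terminate");
  }
  // downward sweep
  q = qm;
  for (int Ni = Nm - 1; Ni >= n; --Ni) {
    q = (qf > 0) ? q / qf : std::exp(-c.lamM * Ni);
    double lti = log_term(c, Ni, q);
    double rel = lti - ltm;
    if (std::isnan(rel) || rel < LOG_REL_TOL) break;
    s += std::exp(rel);
    if (++guard > 10000000L) Rcpp::stop("latent-N summation did not terminate");
  }

  if (s <= 0.0) return R_NegInf;
  return ltm + std::log(s);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_cell_marginal(IntegerVector n, IntegerVector a,
                                NumericVector D, NumericVector r,
                                NumericVector lam, IntegerVector L,
                                NumericVector T, double M, bool integrated) {
  int m = n.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = cell_marginal(n[i], a[i], D[i], r[i], lam[i], L[i], T[i], M,
                           integrated);
  return out;
}

// Per-record capture-history log-likelihood: truncated exponential density
// of the first-capture time on [0, T) plus Poisson recaptures over the
// remaining exposure r (T - c).
static double hist_ll(double cc, int y, double r, double T) {
  if (cc < 0 || cc >= T) return R_NaN;
  if (r <= 0.0) return R_NegInf;
  double l1mp = std::log(-std::expm1(-r * T)); // log(1 - e^{-rT})
  double ll = std::log(r) - r * cc - l1mp;
  double mu = r * (T - cc);
  ll += -mu - lgam1(y);
  if (y > 0) ll += y * std::log(mu);
  return ll;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_hist_loglik(IntegerVector cell, NumericVector cc,
                              IntegerVector y, NumericVector r_cell,
                              NumericVector T_cell, int ncell) {
  NumericVector out(ncell);
  int m = cell.size();
  for (int k = 0; k < m; ++k) {
    int i = cell[k];
    out[i] += hist_ll(cc[k], y[k], r_cell[i], T_cell[i]);
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_hist_ll_records(NumericVector cc, IntegerVector y,
                                  NumericVector r, NumericVector T) {
  int m = cc.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) out[k] = hist_ll(cc[k], y[k], r[k], T[k]);
  return out;
}

// Inverse-CDF draw from the conditional pmf of N given data and parameters
// for one cell; u is a Uniform(0,1) variate supplied by the caller so all
// randomness stays under R's RNG.
// [[Rcpp::export]]
int cpp_draw_N(double u, int n, int a, double D, double r, double lam,
               int L, double T, double M, bool integrated) {
  if (D <= 0.0) return n;
  if (D > 1e6) Rcpp::stop("expected abundance too large to materialize N");
  CellCtx c;
  c.n = n; c.a = integrated ? a : 0; c.L = integrated ? L : 0;
  c.D = D; c.r = r; c.lam = lam; c.T = T; c.M = M;
  double p = -std::expm1(-r * T);
  c.logD = std::log(D);
  c.l1p = -r * T;
  c.lp = (p > 0) ? std::log(p) : R_NegInf;
  c.lamM = lam * M;
  c.lchooseLa = (c.L > 0) ? (lgam1(c.L) - lgam1(c.a) - lgam1(c.L - c.a)) : 0.0;
  double qf = std::exp(-c.lamM);

  int N = std::max(n, (int)D);
  double q = std::exp(-c.lamM * N);
  double lt = log_term(c, N, q);
  for (;;) {
    double qn = q * qf;
    double up = log_term(c, N + 1, qn);
    if (up > lt) { N++; q = qn; lt = up; } else break;
  }
  for (;;) {
    if (N <= n) break;
    double qd = (qf > 0) ? q / qf : std::exp(-c.lamM * (N - 1));
    double dn = log_term(c, N - 1, qd);
    if (std::isnan(dn)) break;
    if (dn >= lt) { N--; q = qd; lt = dn; } else break;
  }
  int Nm = N;
  double ltm = lt, qm = q;

  std::vector<double> w; // weights for N = lo..hi
  std::vector<int> idx;
  w.push_back(1.0); idx.push_back(Nm);
  q = qm;
  for (int Ni = Nm + 1;; ++Ni) {
    q *= qf;
    double rel = log_term(c, Ni, q) - ltm;
    if (std::isnan(rel) || rel < LOG_REL_TOL) break;
    w.push_back(std::exp(rel)); idx.push_back(Ni);
  }
  q = qm;
  for (int Ni = Nm - 1; Ni >= n; --Ni) {
    q = (qf > 0) ? q / qf : std::exp(-c.lamM * Ni);
    double rel = log_term(c, Ni, q) - ltm;
    if (std::isnan(rel) || rel < LOG_REL_TOL) break;
    w.push_back(std::exp(rel)); idx.push_back(Ni);
  }
  double tot = 0.0;
  for (double wi : w) tot += wi;
  double target = u * tot, acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (acc >= target) return idx[k];
  }
  return idx.back();
}
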