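#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Breslow partial likelihood machinery for a single binary indicator
// covariate z in {0,1}. All inputs must be sorted by ascending time.
// Tie groups share one denominator (Breslow approximation).

struct TieGroups {
  std::vector<int> risk_start; // first row index of each event-time group
  std::vector<int> d;          // events in the group
  int n;
};

static TieGroups make_groups(const NumericVector &time,
                             const IntegerVector &event) {
  TieGroups g;
  g.n = time.size();
  int i = 0;
  while (i < g.n) {
    int j = i;
    int d = 0;
    while (j < g.n && time[j] == time[i]) {
      if (event[j] == 1) d++;
      j++;
    }
    if (d > 0) {
      g.risk_start.push_back(i);
      g.d.push_back(d);
    }
    i = j;
  }
  return g;
}

// log partial likelihood, gradient and hessian at beta for indicator z,
// given per-group counts m_k = #(z==1 at risk) and n_k = #at risk,
// s1e = sum of z over events.
static void lik_1d(double beta, double s1e, const std::vector<int> &d,
                   const std::vector<int> &nk, const std::vector<int> &mk,
                   double &l, double &grad, double &hess) {
  double eb = std::exp(beta);
  l = beta * s1e;
  grad = s1e;
  hess = 0.0;
  // sum of d_k * log(denom_k), with the common d_k == 1 case accumulated
  // as chunked products (one log per 8 groups) to avoid a log() per group
  double prod = 1.0;
  int ex = 0, in_chunk = 0;
  double logsum = 0.0;
  for (size_t k = 0; k < d.size(); ++k) {
    double denom = (nk[k] - mk[k]) + mk[k] * eb;
    double p = mk[k] * eb / denom;
    grad -= d[k] * p;
    hess -= d[k] * p * (1.0 - p);
    if (d[k] == 1) {
      prod *= denom;
      if (++in_chunk == 8) {
        int e2;
        prod = std::frexp(prod, &e2);
        ex += e2;
        in_chunk = 0;
      }
    } else {
      logsum += d[k] * std::log(denom);
    }
  }
  logsum += std::log(prod) + ex * M_LN2;
  l -= logsum;
}

// Newton-Raphson with step-halving for the 1-d indicator model.
// Returns convergence; fills beta, se, loglik at beta, loglik at 0.
// beta0 warm-starts the iteration (the maximum is unaffected).
static bool fit_1d(double s1e, const std::vector<int> &d,
                   const std::vector<int> &nk, const std::vector<int> &mk,
                   double &beta, double &se, double &ll, double &ll0,
                   double beta0 = 0.0) {
  double g, h, lold;
  lik_1d(0.0, s1e, d, nk, mk, ll0, g, h);
  if (h > -1e-12) { // no information: indicator constant over risk sets
    beta = 0.0;
    se = R_PosInf;
    ll = ll0;
    return false;
  }
  beta = beta0;
  if (beta0 != 0.0) {
    lik_1d(beta, s1e, d, nk, mk, lold, g, h);
    if (h > -1e-12 || lold < ll0) { // bad start: fall back to 0
      beta = 0.0;
      lik_1d(0.0, s1e, d, nk, mk, lold, g, h);
    }
  } else {
    lold = ll0;
  }
  bool converged = false;
  for (int it = 0; it < 60; ++it) {
    double step = -g / h;
    // quadratic-predicted gain; below tolerance the current point is the
    // maximum to within the convergence criterion
    if (0.5 * g * step < 1e-9) {
      converged = true;
      break;
    }
    double bnew = beta + step;
    double lnew, gn, hn;
    lik_1d(bnew, s1e, d, nk, mk, lnew, gn, hn);
    int halv = 0;
    while (lnew < lold && halv < 30) {
      step *= 0.5;
      bnew = beta + step;
      lik_1d(bnew, s1e, d, nk, mk, lnew, gn, hn);
      halv++;
    }
    beta = bnew;
    g = gn;
    h = hn;
    if (std::fabs(beta) > 15.0) { // monotone likelihood
      converged = false;
      break;
    }
    if (std::fabs(lnew - lold) < 1e-9) {
      lold = lnew;
      converged = true;
      break;
    }
    lold = lnew;
  }
  ll = lold;
  se = (h < 0) ? std::sqrt(-1.0 / h) : R_PosInf;
  return converged;
}

// [[Rcpp::export]]
List cox1_indicator_cpp(NumericVector time, IntegerVector event,
                        IntegerVector z) {
  TieGroups g = make_groups(time, event);
  int n = g.n;
  size_t K = g.d.size();
  // suffix counts of z
  std::vector<int> suff(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) suff[i] = suff[i + 1] + (z[i] == 1);
  std::vector<int> nk(K), mk(K);
  double s1e = 0.0;
  for (int i = 0; i < n; ++i)
    if (event[i] == 1 && z[i] == 1) s1e += 1.0;
  for (size_t k = 0; k < K; ++k) {
    nk[k] = n - g.risk_start[k];
    mk[k] = suff[g.risk_start[k]];
  }
  double beta, se, ll, ll0;
  bool conv = fit_1d(s1e, g.d, nk, mk, beta, se, ll, ll0);
  return List::create(_["beta"] = beta, _["se"] = se, _["loglik"] = ll,
                      _["loglik0"] = ll0, _["lr"] = 2.0 * (ll - ll0),
                      _["converged"] = conv);
}

struct ScanResult {
  double best_stat;
  double best_thr;
  double best_beta;
  double best_se;
  int best_idx; // index into thresholds, -1 if none admissible/converged
  int n_admissible;
};

// Scan all midpoint thresholds of x (I(x > thr) indicator). Admissible:
// both sides >= min_subj subjects and >= min_events events. Ties in the
// statistic (within 1e-12) break toward the smaller threshold.
static ScanResult scan_core(const NumericVector &time,
                            const IntegerVector &event,
                            const std::vector<double> &x, int min_subj,
                            int min_events, const TieGroups &g,
                            std::vector<double> *all_stats,
                            std::vector<double> *all_thr) {
  int n = g.n;
  // distinct sorted values of x
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  std::vector<double> uniq;
  for (int i = 0; i < n; ++i)
    if (i == 0 || xs[i] != xs[i - 1]) uniq.push_back(xs[i]);
  ScanResult res;
  res.best_stat = -1.0;
  res.best_thr = NA_REAL;
  res.best_beta = NA_REAL;
  res.best_se = NA_REAL;
  res.best_idx = -1;
  res.n_admissible = 0;
  if (uniq.size() < 2) return res;

  size_t K = g.d.size();
  std::vector<int> nk(K), mk(K);
  for (size_t k = 0; k < K; ++k) nk[k] = n - g.risk_start[k];
  std::vector<int> suff(n + 1, 0);

  int tot_ev = 0;
  for (int i = 0; i < n; ++i) tot_ev += event[i];

  double warm = 0.0; // previous threshold's solution seeds the next
  for (size_t u = 0; u + 1 < uniq.size(); ++u) {
    double thr = 0.5 * (uniq[u] + uniq[u + 1]);
    int left_n = 0, left_ev = 0;
    double s1e = 0.0;
    for (int i = 0; i < n; ++i) {
      if (x[i] <= thr) {
        left_n++;
        if (event[i] == 1) left_ev++;
      } else if (event[i] == 1) {
        s1e += 1.0;
      }
    }
    int right_n = n - left_n, right_ev = tot_ev - left_ev;
    if (left_n < min_subj || right_n < min_subj || left_ev < min_events ||
        right_ev < min_events)
      continue;
    res.n_admissible++;
    // suffix counts of I(x > thr) in time order
    suff[n] = 0;
    for (int i = n - 1; i >= 0; --i) suff[i] = suff[i + 1] + (x[i] > thr);
    for (size_t k = 0; k < K; ++k) mk[k] = suff[g.risk_start[k]];
    double beta, se, ll, ll0;
    bool conv = fit_1d(s1e, g.d, nk, mk, beta, se, ll, ll0, warm);
    if (!conv) {
      warm = 0.0;
      continue;
    }
    warm = beta;
    double stat = 2.0 * (ll - ll0);
    if (all_stats) {
      all_stats->push_back(stat);
      all_thr->push_back(thr);
    }
    if (stat > res.best_stat + 1e-12) {
      res.best_stat = stat;
      res.best_thr = thr;
      res.best_beta = beta;
      res.best_se = se;
      res.best_idx = (int)u;
    }
  }
  return res;
}

// [[Rcpp::export]]
List cox1_scan_cpp(NumericVector time, IntegerVector event, NumericVector x,
                   int min_subj, int min_events, bool return_all = false) {
  TieGroups g = make_groups(time, event);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> stats, thrs;
  ScanResult res =
      scan_core(time, event, xv, min_subj, min_events, g,
                return_all ? &stats : (std::vector<double> *)nullptr,
                return_all ? &thrs : (std::vector<double> *)nullptr);
  List out = List::create(
      _["stat"] = res.best_stat, _["threshold"] = res.best_thr,
      _["beta"] = res.best_beta, _["se"] = res.best_se,
      _["n_admissible"] = res.n_admissible,
      _["found"] = (res.best_idx >= 0));
  if (return_all) {
    out["all_stats"] = wrap(stats);
    out["all_thresholds"] = wrap(thrs);
  }
  return out;
}

// Permutation null of T_max: shuffle x among rows (outcomes fixed) B times,
// re-scan, record the max statistic (-1 when no admissible converged split).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cox1_perm_tmax_cpp(NumericVector time, IntegerVector event,
                                 NumericVector x, int B, int min_subj,
                                 int min_events) {
  TieGroups g = make_groups(time, event);
  int n = g.n;
  std::vector<double> xp(x.begin(), x.end());
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates using R's uniform stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xp[i], xp[j]);
    }
    ScanResult res = scan_core(time, event, xp, min_subj, min_events, g,
                               nullptr, nullptr);
    out[b] = res.best_stat; // -1 if nothing admissible/converged
  }
  return out;
}
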