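#include <Rcpp.h>
using namespace Rcpp;

// Hartigan's dip statistic.
//
// The dip of an empirical distribution function F_n is the smallest sup-norm
// distance between F_n and any unimodal distribution function G (convex on
// (-inf, m], concave on [m, inf); G may carry an atom at the mode).
//
// Characterisation used here (distinct sorted values v_1..v_m, cumulative
// ECDF heights c_i, c_0 = 0): sup|F_n - G| <= d iff the values g_i = G(v_i)
// can be chosen with
//   g_i in [lo_i, hi_i],  lo_i = max(0, c_i - d),  hi_i = min(1, c_{i-1} + d)
// such that for some split index k the prefix (g_1..g_k) is convex and the
// suffix (g_k..g_m) is concave (the mode sits just right of v_k; an upward
// jump of G at the mode absorbs the junction kink).  Convex values within
// bands exist iff every lower bound lies below the chord of the surrounding
// upper bounds; with a forced endpoint value v at k the chord conditions into
// v give a minimal feasible endpoint alpha_k, and symmetrically a maximal
// feasible suffix start beta_k.  Feasibility at level d is then
//   exists k : prefix bands convex-feasible on 1..k-1,
//              suffix bands concave-feasible on k+1..m,
//              alpha_k <= beta_k.
// The dip is found by bisection on d (it is the threshold of feasibility).

static bool dip_feasible(const std::vector<double>& v,
                         const std::vector<double>& c,
                         double d) {
  const int m = (int)v.size();
  std::vector<double> lo(m), hi(m);
  for (int i = 0; i < m; ++i) {
    lo[i] = std::max(0.0, c[i + 1] - d);
    hi[i] = std::min(1.0, c[i] + d);
    if (lo[i] > hi[i]) return false;
  }
  if (m == 1) return true;

  // s_j = max_{i<j} (lo_j - hi_i) / (v_j - v_i): steepest chord forced into
  // any later point by convexity through (i, j).
  // alpha_l = max(lo_l, max_{j<l} lo_j + s_j (v_l - v_j)).
  std::vector<double> alpha(m), beta(m);
  std::vector<double> s(m, R_NegInf), w(m, R_NegInf);
  for (int j = 1; j < m; ++j)
    for (int i = 0; i < j; ++i)
      s[j] = std::max(s[j], (lo[j] - hi[i]) / (v[j] - v[i]));
  for (int j = 0; j < m - 1; ++j)
    for (int i = j + 1; i < m; ++i)
      w[j] = std::max(w[j], (lo[i] - hi[j]) / (v[i] - v[j]));

  alpha[0] = lo[0];
  for (int l = 1; l < m; ++l) {
    double a = lo[l];
    for (int j = 1; j < l; ++j)
      a = std::max(a, lo[j] + s[j] * (v[l] - v[j]));
    alpha[l] = a;
  }
  beta[m - 1] = hi[m - 1];
  for (int l = m - 2; l >= 0; --l) {
    double b = hi[l];
    for (int j = l + 1; j < m - 1; ++j)
      b = std::min(b, hi[j] - w[j] * (v[j] - v[l]));
    beta[l] = b;
  }

  // prefOK[k]: all alpha_l <= hi_l for l <= k (prefix 1..k+1's interior
  // convex band conditions); suffOK mirrored.
  std::vector<char> prefOK(m), suffOK(m);
  bool ok = true;
  for (int l = 0; l < m; ++l) {
    if (alpha[l] > hi[l] + 1e-15) ok = false;
    prefOK[l] = ok;
  }
  ok = true;
  for (int l = m - 1; l >= 0; --l) {
    if (beta[l] < lo[l] - 1e-15) ok = false;
    suffOK[l] = ok;
  }

  for (int k = 0; k < m; ++k) {
    bool pre = (k == 0) ? true : prefOK[k - 1];
    bool suf = (k == m - 1) ? true : suffOK[k + 1];
    if (pre && suf && alpha[k] <= beta[k] + 1e-15) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 2) return 0.0;
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  // collapse ties
  std::vector<double> v;
  std::vector<double> c;  // c[0] = 0, c[i] = ECDF height after v_i
  c.push_back(0.0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    v.push_back(xs[i]);
    c.push_back((double)j / n);
    i = j;
  }
  if (v.size() == 1) return 0.0;

  double d_lo = 0.0, d_hi = 0.25 + 1.0 / n;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (d_lo + d_hi);
    if (dip_feasible(v, c, mid)) d_hi = mid; else d_lo = mid;
  }
  return 0.5 * (d_lo + d_hi);
}

// Refractory thinning of a sorted spike-time vector: walk left to right,
// drop any spike closer than `refractory` ms to the last kept spike.
// `keep_first` marks indices that always win conflicts (evoked spikes):
// a background spike within `refractory` of a kept evoked spike is dropped
// even if it precedes it.
// [[Rcpp::export(name = ".thin_refractory_cpp")]]
NumericVector thin_refractory_cpp(NumericVector times, LogicalVector priority,
                                  double refractory) {
  const int n = times.size();
  std::vector<double> out;
  out.reserve(n);
  // first pass: drop non-priority spikes within `refractory` of any priority spike
  std::vector<double> prio;
  for (int i = 0; i < n; ++i) if (priority[i]) prio.push_back(times[i]);
  std::vector<double> t2;
  std::vector<char> p2;
  for (int i = 0; i < n; ++i) {
    if (!priority[i]) {
      bool clash = false;
      for (size_t j = 0; j < prio.size(); ++j)
        if (std::fabs(times[i] - prio[j]) < refractory) { clash = true; break; }
      if (clash) continue;
    }
    t2.push_back(times[i]);
    p2.push_back(priority[i] ? 1 : 0);
  }
  // second pass: sequential thinning of what remains
  double last = R_NegInf;
  for (size_t i = 0; i < t2.size(); ++i) {
    if (t2[i] - last >= refractory) {
      out.push_back(t2[i]);
      last = t2[i];
    }
  }
  return wrap(out);
}
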