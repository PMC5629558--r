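#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Single-covariate Cox partial likelihood machinery used by the exhaustive
// cut-off scans. Ties are handled with the Efron approximation. Everything
// operates on samples pre-sorted by ascending survival time; risk sets are
// suffix counts, so building the per-event-time statistics for one candidate
// split is O(n).

// Per distinct event time: at-risk and death counts split by group.
struct Blocks {
  std::vector<double> r1, r0, d1, d0;
  double D1 = 0.0, D0 = 0.0;
};

// status codes: 0 ok, 1 no events in one group, 2 monotone likelihood
// (separation), 3 not converged, 4 no contrast in the indicator
struct Fit1 {
  double beta = NA_REAL, se = NA_REAL, loglik = NA_REAL;
  int status = 3, iter = 0;
};

static void build_blocks(const std::vector<double>& time,
                         const std::vector<int>& event,
                         const std::vector<int>& z, Blocks& bl) {
  const int n = (int)time.size();
  bl.r1.clear(); bl.r0.clear(); bl.d1.clear(); bl.d0.clear();
  bl.D1 = 0.0; bl.D0 = 0.0;
  std::vector<int> suf1(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) suf1[i] = suf1[i + 1] + z[i];
  int i = 0;
  while (i < n) {
    int j = i;
    double d1 = 0.0, d0 = 0.0;
    while (j < n && time[j] == time[i]) {
      if (event[j]) { if (z[j]) d1 += 1.0; else d0 += 1.0; }
      ++j;
    }
    if (d1 + d0 > 0.0) {
      bl.r1.push_back((double)suf1[i]);
      bl.r0.push_back((double)(n - i - suf1[i]));
      bl.d1.push_back(d1);
      bl.d0.push_back(d0);
      bl.D1 += d1; bl.D0 += d0;
    }
    i = j;
  }
}

// Efron score U and information I at beta (no log calls: the scans only
// need the root of the score and the curvature there)
static void efron_UI(const Blocks& bl, double b, double* U, double* I) {
  const double eb = std::exp(b);
  double u = bl.D1, info = 0.0;
  const int G = (int)bl.r1.size();
  for (int g = 0; g < G; ++g) {
    const double A = bl.r1[g] * eb + bl.r0[g];
    const double a1 = bl.r1[g] * eb;
    const int d = (int)(bl.d1[g] + bl.d0[g] + 0.5);
    if (d == 1) {
      const double q = a1 / A;
      u -= q;
      info += q - q * q;
    } else {
      const double B = bl.d1[g] * eb + bl.d0[g];
      const double b1 = bl.d1[g] * eb;
      for (int l = 0; l < d; ++l) {
        const double f = (double)l / (double)d;
        const double q = (a1 - f * b1) / (A - f * B);
        u -= q;
        info += q - q * q;
      }
    }
  }
  *U = u; *I = info;
}

// Efron partial log-likelihood (only reported by the single-fit entry point)
static double efron_ll(const Blocks& bl, double b) {
  const double eb = std::exp(b);
  double ll = b * bl.D1;
  const int G = (int)bl.r1.size();
  for (int g = 0; g < G; ++g) {
    const double A = bl.r1[g] * eb + bl.r0[g];
    const double B = bl.d1[g] * eb + bl.d0[g];
    const int d = (int)(bl.d1[g] + bl.d0[g] + 0.5);
    for (int l = 0; l < d; ++l)
      ll -= std::log(A - ((double)l / (double)d) * B);
  }
  return ll;
}

// Safeguarded Newton on the score: the partial log-likelihood is strictly
// concave in beta, so U is strictly decreasing; keep a sign bracket and
// bisect whenever a Newton step leaves it.
static Fit1 cox_fit_blocks(const Blocks& bl, double b0) {
  Fit1 f;
  if (bl.D1 < 1.0 || bl.D0 < 1.0) { f.status = 1; return f; }
  double b = R_finite(b0) ? b0 : 0.0;
  double lo = -16.0, hi = 16.0;
  double U, I;
  for (int it = 1; it <= 60; ++it) {
    f.iter = it;
    efron_UI(bl, b, &U, &I);
    if (!(I > 0.0)) { f.status = 2; return f; }
    if (std::fabs(U) < 1e-11) {          // at the root: finalize here
      f.beta = b; f.se = 1.0 / std::sqrt(I); f.status = 0;
      return f;
    }
    if (U > 0) lo = b; else hi = b;
    double step = U / I;
    if (step > 1.0) step = 1.0;
    if (step < -1.0) step = -1.0;
    double bn = b + step;
    if (bn <= lo || bn >= hi) bn = 0.5 * (lo + hi);  // bisection safeguard
    const double moved = std::fabs(bn - b);
    b = bn;
    if (std::fabs(b) > 15.0) { f.status = 2; f.beta = b; return f; }
    if (moved < 1e-10 * (std::fabs(b) + 1e-3)) {
      efron_UI(bl, b, &U, &I);
      if (!(I > 0.0)) { f.status = 2; return f; }
      f.beta = b; f.se = 1.0 / std::sqrt(I); f.status = 0;
      return f;
    }
  }
  f.status = 3;
  return f;
}

static double wald_p(double beta, double se) {
  if (!R_finite(beta) || !R_finite(se) || se <= 0) return NA_REAL;
  return 2.0 * R::pnorm(-std::fabs(beta / se), 0.0, 1.0, 1, 0);
}

// order() by ascending time, stable
static std::vector<int> time_order(const NumericVector& time) {
  std::vector<int> ord(time.size());
  for (int i = 0; i < (int)ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  return ord;
}

// [[Rcpp::export]]
List cox1_fit_cpp(NumericVector time, IntegerVector event, IntegerVector z) {
  const int n = time.size();
  std::vector<int> ord = time_order(time);
  std::vector<double> ts(n);
  std::vector<int> es(n), zs(n);
  int n1 = 0;
  for (int i = 0; i < n; ++i) {
    ts[i] = time[ord[i]]; es[i] = event[ord[i]]; zs[i] = z[ord[i]];
    n1 += zs[i];
  }
  if (n1 == 0 || n1 == n)
    return List::create(_["beta"] = NA_REAL, _["se"] = NA_REAL,
                        _["p"] = NA_REAL, _["loglik"] = NA_REAL,
                        _["status"] = 4, _["iter"] = 0);
  Blocks bl;
  build_blocks(ts, es, zs, bl);
  Fit1 f = cox_fit_blocks(bl, 0.0);
  const double ll = (f.status == 0) ? efron_ll(bl, f.beta) : NA_REAL;
  return List::create(_["beta"] = f.beta, _["se"] = f.se,
                      _["p"] = wald_p(f.beta, f.se), _["loglik"] = ll,
                      _["status"] = f.status, _["iter"] = f.iter);
}

// Exhaustive 1D cut-off scan: for every candidate c evaluate the Cox-Wald
// test of the indicator (x > c). Admissible candidates keep at least
// min_group samples and at least one event on each side.
// [[Rcpp::export]]
DataFrame scan1d_cpp(NumericVector time, IntegerVector event, NumericVector x,
                     NumericVector candidates, int min_group) {
  const int n = time.size(), m = candidates.size();
  std::vector<int> ord = time_order(time);
  std::vector<double> ts(n), xs(n);
  std::vector<int> es(n), zs(n);
  for (int i = 0; i < n; ++i) {
    ts[i] = time[ord[i]]; es[i] = event[ord[i]]; xs[i] = x[ord[i]];
  }
  NumericVector beta(m, NA_REAL), se(m, NA_REAL), p(m, NA_REAL);
  IntegerVector nh(m), ev_h(m), status(m);
  LogicalVector adm(m);
  Blocks bl;
  double warm = 0.0;
  for (int c = 0; c < m; ++c) {
    const double cut = candidates[c];
    int n1 = 0, e1 = 0, e0 = 0;
    for (int i = 0; i < n; ++i) {
      zs[i] = xs[i] > cut ? 1 : 0;
      if (zs[i]) { ++n1; e1 += es[i]; } else e0 += es[i];
    }
    nh[c] = n1; ev_h[c] = e1;
    bool ok = n1 >= min_group && (n - n1) >= min_group && e1 >= 1 && e0 >= 1;
    adm[c] = ok;
    if (!ok) { status[c] = 1; continue; }
    build_blocks(ts, es, zs, bl);
    Fit1 f = cox_fit_blocks(bl, warm);
    status[c] = f.status;
    if (f.status == 0) {
      beta[c] = f.beta; se[c] = f.se; p[c] = wald_p(f.beta, f.se);
      warm = f.beta;
    }
  }
  return DataFrame::create(_["cutoff"] = candidates, _["n_high"] = nh,
                           _["events_high"] = ev_h, _["beta"] = beta,
                           _["se"] = se, _["p"] = p, _["status"] = status,
                           _["admissible"] = adm);
}

// minimum admissible Wald p over a candidate grid (1.0 when nothing fits)
static double scan_min_p(const std::vector<double>& ts,
                         const std::vector<int>& es,
                         const std::vector<double>& xs,
                         const NumericVector& candidates, int min_group) {
  const int n = (int)ts.size(), m = candidates.size();
  std::vector<int> zs(n);
  Blocks bl;
  double best = 1.0, warm = 0.0;
  for (int c = 0; c < m; ++c) {
    const double cut = candidates[c];
    int n1 = 0, e1 = 0, e0 = 0;
    for (int i = 0; i < n; ++i) {
      zs[i] = xs[i] > cut ? 1 : 0;
      if (zs[i]) { ++n1; e1 += es[i]; } else e0 += es[i];
    }
    if (n1 < min_group || (n - n1) < min_group || e1 < 1 || e0 < 1) continue;
    build_blocks(ts, es, zs, bl);
    Fit1 f = cox_fit_blocks(bl, warm);
    if (f.status != 0) continue;
    warm = f.beta;
    const double pv = wald_p(f.beta, f.se);
    if (R_finite(pv) && pv < best) best = pv;
  }
  return best;
}

// Null distribution of the scan minimum: for each row of `perms` (a 1-based
// permutation of the samples) shuffle x against (time, event) and return
// the minimized admissible Wald p.
// [[Rcpp::export]]
NumericVector scan1d_perm_minp_cpp(NumericVector time, IntegerVector event,
                                   NumericVector x, NumericVector candidates,
                                   int min_group, IntegerMatrix perms) {
  const int n = time.size(), B = perms.nrow();
  std::vector<int> ord = time_order(time);
  std::vector<double> ts(n), xs(n);
  std::vector<int> es(n);
  for (int i = 0; i < n; ++i) { ts[i] = time[ord[i]]; es[i] = event[ord[i]]; }
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = x[perms(b, ord[i]) - 1];
    out[b] = scan_min_p(ts, es, xs, candidates, min_group);
  }
  return out;
}

// Paired scan: joint search over (c1, c2) cut-off grids and the supplied
// quadrant risk designs (rows of `designs`, one 0/1 entry per quadrant in
// the order low/low, low/high, high/low, high/high; 1 = higher-risk).
// Returns the global minimizer with deterministic tie-break (ascending c1,
// then c2, then design row). With full = true also returns the whole table.
// [[Rcpp::export]]
List scan2d_cpp(NumericVector time, IntegerVector event, NumericVector x1,
                NumericVector x2, NumericVector c1s, NumericVector c2s,
                IntegerMatrix designs, int min_group, bool full = false) {
  const int n = time.size(), m1 = c1s.size(), m2 = c2s.size();
  const int nd = designs.nrow();
  std::vector<int> ord = time_order(time);
  std::vector<double> ts(n), xs1(n), xs2(n);
  std::vector<int> es(n);
  for (int i = 0; i < n; ++i) {
    ts[i] = time[ord[i]]; es[i] = event[ord[i]];
    xs1[i] = x1[ord[i]]; xs2[i] = x2[ord[i]];
  }
  // block starts (distinct times with >= 1 death) are cut-off independent
  std::vector<int> bstart, bend;
  {
    int i = 0;
    while (i < n) {
      int j = i; bool any = false;
      while (j < n && ts[j] == ts[i]) { if (es[j]) any = true; ++j; }
      if (any) { bstart.push_back(i); bend.push_back(j); }
      i = j;
    }
  }
  const int nb = (int)bstart.size();
  std::vector<int> quad(n);
  std::vector<double> rq(4 * nb), dq(4 * nb), sufAt(4 * n);
  double best_p = R_PosInf;
  double best_c1 = NA_REAL, best_c2 = NA_REAL, best_beta = NA_REAL,
         best_se = NA_REAL;
  int best_design = NA_INTEGER, best_nhigh = NA_INTEGER, n_adm = 0;
  std::vector<double> tab;  // rows: c1,c2,design,p,beta,se,n_high
  Blocks bl;
  bl.r1.resize(nb); bl.r0.resize(nb); bl.d1.resize(nb); bl.d0.resize(nb);
  std::vector<double> warm(nd, 0.0);
  for (int a = 0; a < m1; ++a) {
    const double c1 = c1s[a];
    for (int b = 0; b < m2; ++b) {
      const double c2 = c2s[b];
      int nq[4] = {0, 0, 0, 0}, eq[4] = {0, 0, 0, 0};
      for (int i = 0; i < n; ++i) {
        quad[i] = 2 * (xs1[i] > c1 ? 1 : 0) + (xs2[i] > c2 ? 1 : 0);
        ++nq[quad[i]];
        eq[quad[i]] += es[i];
      }
      {
        double suf[4] = {0, 0, 0, 0};
        for (int i = n - 1; i >= 0; --i) {
          suf[quad[i]] += 1.0;
          sufAt[4 * i + 0] = suf[0]; sufAt[4 * i + 1] = suf[1];
          sufAt[4 * i + 2] = suf[2]; sufAt[4 * i + 3] = suf[3];
        }
        for (int g = 0; g < nb; ++g) {
          double dd[4] = {0, 0, 0, 0};
          for (int j = bstart[g]; j < bend[g]; ++j)
            if (es[j]) dd[quad[j]] += 1.0;
          for (int q = 0; q < 4; ++q) {
            rq[4 * g + q] = sufAt[4 * bstart[g] + q];
            dq[4 * g + q] = dd[q];
          }
        }
      }
      for (int d = 0; d < nd; ++d) {
        int nhigh = 0, ehigh = 0, etot = 0;
        for (int q = 0; q < 4; ++q) {
          etot += eq[q];
          if (designs(d, q) == 1) { nhigh += nq[q]; ehigh += eq[q]; }
        }
        const int nlow = n - nhigh;
        if (nhigh < min_group || nlow < min_group || ehigh < 1 ||
            etot - ehigh < 1)
          continue;
        ++n_adm;
        bl.D1 = 0.0; bl.D0 = 0.0;
        for (int g = 0; g < nb; ++g) {
          double r1 = 0, r0 = 0, d1 = 0, d0 = 0;
          for (int q = 0; q < 4; ++q) {
            if (designs(d, q) == 1) { r1 += rq[4 * g + q]; d1 += dq[4 * g + q]; }
            else { r0 += rq[4 * g + q]; d0 += dq[4 * g + q]; }
          }
          bl.r1[g] = r1; bl.r0[g] = r0; bl.d1[g] = d1; bl.d0[g] = d0;
          bl.D1 += d1; bl.D0 += d0;
        }
        Fit1 f = cox_fit_blocks(bl, warm[d]);
        if (f.status != 0) { warm[d] = 0.0; continue; }
        warm[d] = f.beta;
        const double pv = wald_p(f.beta, f.se);
        if (full) {
          tab.push_back(c1); tab.push_back(c2); tab.push_back(d + 1);
          tab.push_back(pv); tab.push_back(f.beta); tab.push_back(f.se);
          tab.push_back((double)nhigh);
        }
        if (R_finite(pv) && pv < best_p) {
          best_p = pv; best_c1 = c1; best_c2 = c2; best_design = d + 1;
          best_beta = f.beta; best_se = f.se; best_nhigh = nhigh;
        }
      }
    }
  }
  List out = List::create(
      _["c1"] = best_c1, _["c2"] = best_c2, _["design"] = best_design,
      _["p"] = R_finite(best_p) ? best_p : NA_REAL, _["beta"] = best_beta,
      _["se"] = best_se, _["n_high"] = best_nhigh,
      _["n_admissible"] = n_adm);
  if (full) {
    const int nr = (int)tab.size() / 7;
    NumericMatrix M(nr, 7);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < 7; ++c) M(r, c) = tab[7 * r + c];
    colnames(M) = CharacterVector::create("c1", "c2", "design", "p", "beta",
                                          "se", "n_high");
    out["table"] = M;
  }
  return out;
}

// Repeated k-means with Manhattan distance and component-wise median
// centroid update. Rows of X are the clustered objects. init_idx supplies
// the (1-based) seeding rows for each run so that all randomness stays with
// the caller. Runs that do not stabilize within max_iter are dropped.
// Returns the co-assignment count matrix and the number of completed runs.
// [[Rcpp::export]]
List kmeans_consensus_cpp(NumericMatrix X, IntegerMatrix init_idx,
                          int max_iter) {
  const int n = X.nrow(), p = X.ncol(), k = init_idx.ncol(),
            runs = init_idx.nrow();
  NumericMatrix co(n, n);
  IntegerVector lab_last(n);
  int completed = 0;
  std::vector<int> lab(n), newlab(n);
  std::vector<double> centers(k * p), buf(n);
  for (int run = 0; run < runs; ++run) {
    for (int c = 0; c < k; ++c)
      for (int j = 0; j < p; ++j) centers[c * p + j] = X(init_idx(run, c) - 1, j);
    std::fill(lab.begin(), lab.end(), -1);
    bool converged = false;
    for (int it = 0; it < max_iter; ++it) {
      // assignment
      for (int i = 0; i < n; ++i) {
        double bestd = R_PosInf; int bestc = 0;
        for (int c = 0; c < k; ++c) {
          double d = 0.0;
          for (int j = 0; j < p; ++j) d += std::fabs(X(i, j) - centers[c * p + j]);
          if (d < bestd) { bestd = d; bestc = c; }
        }
        newlab[i] = bestc;
      }
      // empty-cluster fix: seed with the worst-fit object
      for (int c = 0; c < k; ++c) {
        int cnt = 0;
        for (int i = 0; i < n; ++i) if (newlab[i] == c) ++cnt;
        if (cnt == 0) {
          double worst = -1.0; int wi = 0;
          for (int i = 0; i < n; ++i) {
            double d = 0.0;
            const int cc = newlab[i];
            for (int j = 0; j < p; ++j)
              d += std::fabs(X(i, j) - centers[cc * p + j]);
            if (d > worst) { worst = d; wi = i; }
          }
          newlab[wi] = c;
        }
      }
      if (newlab == lab) { converged = true; break; }
      lab = newlab;
      // median update
      for (int c = 0; c < k; ++c) {
        int cnt = 0;
        for (int i = 0; i < n; ++i) if (lab[i] == c) ++cnt;
        if (cnt == 0) continue;
        for (int j = 0; j < p; ++j) {
          int m = 0;
          for (int i = 0; i < n; ++i) if (lab[i] == c) buf[m++] = X(i, j);
          std::nth_element(buf.begin(), buf.begin() + (m - 1) / 2,
                           buf.begin() + m);
          double med = buf[(m - 1) / 2];
          if (m % 2 == 0) {
            std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
            med = 0.5 * (med + buf[m / 2]);
          }
          centers[c * p + j] = med;
        }
      }
    }
    if (!converged) continue;
    ++completed;
    for (int i = 0; i < n; ++i) {
      lab_last[i] = lab[i] + 1;
      for (int j = i; j < n; ++j)
        if (lab[i] == lab[j]) { co(i, j) += 1.0; if (j != i) co(j, i) += 1.0; }
    }
  }
  return List::create(_["counts"] = co, _["completed"] = completed,
                      _["last_labels"] = lab_last);
}
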