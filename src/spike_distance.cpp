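#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Restrict a sorted spike vector to [t0, t1] and add auxiliary edge spikes.
// Duplicates (including spikes coinciding with an edge) collapse; times are
// assumed sorted increasing (validated on the R side).
static std::vector<double> augment(const NumericVector& t, double t0, double t1) {
  std::vector<double> v;
  v.reserve(t.size() + 2);
  v.push_back(t0);
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    double x = t[i];
    if (x < t0 || x > t1) continue;
    if (x > v.back()) v.push_back(x);
  }
  if (v.back() < t1) v.push_back(t1);
  return v;
}

// ISI-distance: time average of |x_isi - y_isi| / max(x_isi, y_isi)
// over the union of augmented spike times (piecewise constant).
static double isi_scalar(const std::vector<double>& x, const std::vector<double>& y) {
  double t0 = x.front(), t1 = x.back();
  size_t ix = 0, iy = 0;
  double t = t0, acc = 0.0;
  while (t < t1) {
    double xi = x[ix + 1] - x[ix];
    double yi = y[iy + 1] - y[iy];
    double nxt = std::min(x[ix + 1], y[iy + 1]);
    acc += std::fabs(xi - yi) / std::max(xi, yi) * (nxt - t);
    if (x[ix + 1] <= nxt && ix + 2 < x.size()) ++ix;
    if (y[iy + 1] <= nxt && iy + 2 < y.size()) ++iy;
    if (nxt <= t) break; // safety against FP stalls
    t = nxt;
  }
  return acc / (t1 - t0);
}

// distance from s to the nearest element of sorted v
static double nearest_dist(const std::vector<double>& v, double s) {
  std::vector<double>::const_iterator it = std::lower_bound(v.begin(), v.end(), s);
  double d = R_PosInf;
  if (it != v.end()) d = std::min(d, *it - s);
  if (it != v.begin()) d = std::min(d, s - *(it - 1));
  return d;
}

// SPIKE profile value at time t inside a segment where the bracketing spikes
// are (xp, xf) for train x and (yp, yf) for train y.
static inline double spike_val(double t,
                               double xp, double xf, double dxp, double dxf,
                               double yp, double yf, double dyp, double dyf) {
  double xisi = xf - xp, yisi = yf - yp;
  double Sx = (dxp * (xf - t) + dxf * (t - xp)) / xisi;
  double Sy = (dyp * (yf - t) + dyf * (t - yp)) / yisi;
  double m = 0.5 * (xisi + yisi);
  return (Sx * yisi + Sy * xisi) / (2.0 * m * m);
}

// SPIKE-distance: exact time average of the piecewise-linear profile.
static double spike_scalar(const std::vector<double>& x, const std::vector<double>& y) {
  double t0 = x.front(), t1 = x.back();
  // union of breakpoints
  std::vector<double> u;
  u.reserve(x.size() + y.size());
  std::set_union(x.begin(), x.end(), y.begin(), y.end(), std::back_inserter(u));
  double acc = 0.0;
  size_t ix = 0, iy = 0;
  for (size_t k = 0; k + 1 < u.size(); ++k) {
    double a = u[k], b = u[k + 1];
    while (ix + 2 < x.size() && x[ix + 1] <= a) ++ix;
    while (iy + 2 < y.size() && y[iy + 1] <= a) ++iy;
    double xp = x[ix], xf = x[ix + 1];
    double yp = y[iy], yf = y[iy + 1];
    double dxp = nearest_dist(y, xp), dxf = nearest_dist(y, xf);
    double dyp = nearest_dist(x, yp), dyf = nearest_dist(x, yf);
    double va = spike_val(a, xp, xf, dxp, dxf, yp, yf, dyp, dyf);
    double vb = spike_val(b, xp, xf, dxp, dxf, yp, yf, dyp, dyf);
    acc += 0.5 * (va + vb) * (b - a);
  }
  return acc / (t1 - t0);
}

// [[Rcpp::export(name = ".cppBivariateDistance")]]
double cpp_bivariate_distance(NumericVector x, NumericVector y,
                              double t0, double t1, int kind) {
  if (!(t1 > t0)) stop("window must have positive length");
  std::vector<double> xa = augment(x, t0, t1);
  std::vector<double> ya = augment(y, t0, t1);
  if (kind == 0) return isi_scalar(xa, ya);
  return spike_scalar(xa, ya);
}

// Mean over recording sites of the bivariate distance between two trials.
// Each trial is a List of sorted numeric spike-time vectors (one per site).
// [[Rcpp::export(name = ".cppPooledDistance")]]
double cpp_pooled_distance(List a, List b, double t0, double t1, int kind) {
  int n = a.size();
  if (b.size() != n) stop("site count mismatch between trials");
  double acc = 0.0;
  for (int s = 0; s < n; ++s) {
    NumericVector xs = a[s], ys = b[s];
    std::vector<double> xa = augment(xs, t0, t1);
    std::vector<double> ya = augment(ys, t0, t1);
    acc += (kind == 0) ? isi_scalar(xa, ya) : spike_scalar(xa, ya);
  }
  return acc / n;
}

// Mean pooled distance for batches of trial pairs grouped by stimulus pair.
// trials: List (length nTrials) of Lists of per-site spike vectors.
// ti, tj: 1-based trial indices of the sampled cross-trial pairs.
// pairId: 1-based group index (stimulus pair) for each sampled trial pair.
// Returns the per-group mean distance.
// [[Rcpp::export(name = ".cppPairGroupMeans")]]
NumericVector cpp_pair_group_means(List trials, IntegerVector ti, IntegerVector tj,
                                   IntegerVector pairId, int nGroups,
                                   double t0, double t1, int kind) {
  R_xlen_t np = ti.size();
  if (tj.size() != np || pairId.size() != np) stop("pair index length mismatch");
  // pre-augment all trains once
  int nTrials = trials.size();
  std::vector<std::vector<std::vector<double> > > aug(nTrials);
  int nSites = -1;
  for (int i = 0; i < nTrials; ++i) {
    List tr = trials[i];
    if (nSites < 0) nSites = tr.size();
    else if (tr.size() != nSites) stop("inconsistent site counts across trials");
    aug[i].resize(nSites);
    for (int s = 0; s < nSites; ++s) {
      NumericVector v = tr[s];
      aug[i][s] = augment(v, t0, t1);
    }
  }
  std::vector<double> sums(nGroups, 0.0);
  std::vector<int> cnts(nGroups, 0);
  for (R_xlen_t p = 0; p < np; ++p) {
    int i = ti[p] - 1, j = tj[p] - 1, g = pairId[p] - 1;
    if (i < 0 || i >= nTrials || j < 0 || j >= nTrials || g < 0 || g >= nGroups)
      stop("index out of range");
    double acc = 0.0;
    for (int s = 0; s < nSites; ++s)
      acc += (kind == 0) ? isi_scalar(aug[i][s], aug[j][s])
                         : spike_scalar(aug[i][s], aug[j][s]);
    sums[g] += acc / nSites;
    cnts[g] += 1;
  }
  NumericVector out(nGroups);
  for (int g = 0; g < nGroups; ++g)
    out[g] = cnts[g] ? sums[g] / cnts[g] : NA_REAL;
  return out;
}
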