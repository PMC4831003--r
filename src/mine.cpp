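#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Approximate maximal information coefficient (MINE-style grid search).
//
// For every grid shape (a x b) with a*b <= B(n) = n^alpha, the y axis is
// equipartitioned into b rows and the x-axis partition (at most a columns,
// cut only between distinct x values) is optimized by dynamic programming
// over "clumps" of points; the number of clumps is capped at c*a by
// superclumping. Both orientations are searched. The reported value is
// max over shapes of I*(a,b) / log(min(a,b)).

static const double kEps = 1e-12;

static inline double xlogx(double v) { return v > 0 ? v * std::log(v) : 0.0; }

// Equal-frequency rows for y (ties kept together). Returns row id per point
// in the order of the supplied sorted index.
static std::vector<int> equipartition(const std::vector<double>& y_sorted,
                                      int b, int n) {
  std::vector<int> row(n);
  double desired = (double)n / b;
  int cur = 0, filled = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && y_sorted[j] == y_sorted[i]) ++j;  // tie group [i, j)
    int g = j - i;
    // advance row if the current one is full enough and rows remain
    if (filled > 0 && cur < b - 1 &&
        std::fabs(filled + g - desired) > std::fabs(filled - desired)) {
      ++cur;
      filled = 0;
      desired = (double)(n - i) / (b - cur);
    }
    for (int t = i; t < j; ++t) row[t] = cur;
    filled += g;
    i = j;
  }
  return row;
}

// One orientation: rows from y (b of them), optimized columns on x.
// Returns I*(l, b) for every column count l = 2..a in one DP pass
// (out[l - 2] = best mutual information with at most l columns).
static std::vector<double> optimize_axis(const std::vector<double>& x_sorted,
                                         const std::vector<int>& q, int a,
                                         int b, int n, int c) {
  // clumps: maximal runs breakable only between distinct x values, merging
  // adjacent pure runs with the same row label
  std::vector<int> clump_end;  // exclusive end index of each clump
  {
    int i = 0;
    int prev_q = -2;          // row label of previous pure clump, -2 none
    bool prev_pure = false;
    while (i < n) {
      int j = i;
      bool pure = true;
      while (j < n && x_sorted[j] == x_sorted[i]) {
        if (q[j] != q[i]) pure = false;
        ++j;
      }
      if (pure && prev_pure && prev_q == q[i] && !clump_end.empty()) {
        clump_end.back() = j;  // extend previous clump
      } else {
        clump_end.push_back(j);
      }
      prev_pure = pure;
      prev_q = pure ? q[i] : -2;
      i = j;
    }
  }
  int k = clump_end.size();
  // superclumps: cap at c*a boundaries, respecting clump boundaries
  int cap = c * a;
  if (k > cap) {
    std::vector<int> se;
    double step = (double)n / cap;
    double target = step;
    for (int t = 0; t < k; ++t) {
      if (t == k - 1 || clump_end[t] >= target - kEps) {
        se.push_back(clump_end[t]);
        target = clump_end[t] + step;
      }
    }
    clump_end = se;
    k = clump_end.size();
  }
  std::vector<double> out(std::max(a - 1, 0), 0.0);
  if (k < 2 || a < 2) return out;
  // cumulative row counts per clump prefix
  std::vector<std::vector<double>> cum(k + 1, std::vector<double>(b, 0.0));
  {
    int start = 0;
    for (int t = 0; t < k; ++t) {
      cum[t + 1] = cum[t];
      for (int i = start; i < clump_end[t]; ++i) cum[t + 1][q[i]] += 1.0;
      start = clump_end[t];
    }
  }
  auto seg_score = [&](int s, int t) {  // clumps (s, t]
    double m = 0.0, sc = 0.0;
    for (int r = 0; r < b; ++r) {
      double mq = cum[t][r] - cum[s][r];
      sc += xlogx(mq);
      m += mq;
    }
    return sc - xlogx(m);
  };
  int lmax = std::min(a, k);
  // F[t][l]: best score for first t clumps in l columns
  std::vector<std::vector<double>> F(k + 1,
      std::vector<double>(lmax + 1, -std::numeric_limits<double>::infinity()));
  for (int t = 1; t <= k; ++t) F[t][1] = seg_score(0, t);
  for (int l = 2; l <= lmax; ++l) {
    for (int t = l; t <= k; ++t) {
      double best = -std::numeric_limits<double>::infinity();
      for (int s = l - 1; s < t; ++s) {
        double v = F[s][l - 1] + seg_score(s, t);
        if (v > best) best = v;
      }
      F[t][l] = best;
    }
  }
  double hq = 0.0;
  for (int r = 0; r < b; ++r) {
    double nq = cum[k][r];
    if (nq > 0) hq -= (nq / n) * std::log(nq / n);
  }
  // best I with AT MOST l columns is monotone in l; accumulate running max
  double run = 0.0;
  for (int l = 2; l <= a; ++l) {
    if (l <= lmax) {
      double I = hq + F[k][l] / n;
      if (I > run) run = I;
    }
    out[l - 2] = run;
  }
  return out;
}

static double mic_orient(const std::vector<double>& x,
                         const std::vector<double>& y, int n, int B, int c) {
  // sort by x once; per b, rows come from y order
  std::vector<int> ox(n);
  for (int i = 0; i < n; ++i) ox[i] = i;
  std::sort(ox.begin(), ox.end(),
            [&](int i, int j) { return x[i] < x[j]; });
  std::vector<double> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = x[ox[i]];
  std::vector<int> oy(n);
  for (int i = 0; i < n; ++i) oy[i] = i;
  std::sort(oy.begin(), oy.end(),
            [&](int i, int j) { return y[i] < y[j]; });
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = y[oy[i]];

  double best = 0.0;
  for (int b = 2; b <= B / 2; ++b) {
    int amax = B / b;
    if (amax < 2) break;
    std::vector<int> row_sorted = equipartition(ys, b, n);
    std::vector<int> row(n);
    for (int i = 0; i < n; ++i) row[oy[i]] = row_sorted[i];
    std::vector<int> qx(n);
    for (int i = 0; i < n; ++i) qx[i] = row[ox[i]];
    // one DP pass per row count yields I*(l, b) for all column counts l
    std::vector<double> I = optimize_axis(xs, qx, amax, b, n, c);
    for (int a = 2; a <= amax; ++a) {
      double v = I[a - 2] / std::log(std::min(a, b));
      if (v > best) best = v;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".mic_cpp")]]
double mic_cpp(NumericVector x, NumericVector y, double alpha, int c) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  int B = std::max(4, (int)std::floor(std::pow((double)n, alpha)));
  double m1 = mic_orient(xv, yv, n, B, c);
  double m2 = mic_orient(yv, xv, n, B, c);
  double mic = std::max(m1, m2);
  if (mic > 1.0) mic = 1.0;
  return mic;
}
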