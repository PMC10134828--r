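// Maximal information coefficient (MIC) via the characteristic-matrix
// algorithm: equipartition one axis into rows, optimize the other axis'
// column boundaries by dynamic programming over clumps, normalize the best
// mutual information per grid size by log(min(columns, rows)), and take the
// maximum over all grids with (columns x rows) <= B.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

// Greedy equipartition of sorted values into ny rows, keeping ties together.
// Returns row index per (sorted) position.
std::vector<int> equipartition(const std::vector<double>& sorted_vals, int ny) {
  int n = (int)sorted_vals.size();
  std::vector<int> row(n);
  int i = 0, curr = 0, in_row = 0, remaining = n, rows_left = ny;
  double desired = (double)remaining / rows_left;
  while (i < n) {
    int j = i;
    while (j < n && sorted_vals[j] == sorted_vals[i]) ++j;
    int m = j - i;
    if (in_row != 0 && curr < ny - 1 &&
        std::abs(in_row + m - desired) >= std::abs(in_row - desired)) {
      ++curr;
      remaining -= in_row;
      --rows_left;
      in_row = 0;
      desired = (double)remaining / rows_left;
    }
    for (int t = i; t < j; ++t) row[t] = curr;
    in_row += m;
    i = j;
  }
  return row;
}

// Clump boundaries: x-tied points are atomic; consecutive atoms that are pure
// and share the same row merge (an optimal cut never splits them).
// Returns clump sizes and per-clump row counts.
void build_clumps(const std::vector<double>& xs, const std::vector<int>& rows,
                  int ny, std::vector<int>& clump_size,
                  std::vector<std::vector<int> >& clump_rows) {
  int n = (int)xs.size();
  int i = 0;
  int prev_pure_row = -2;  // row of previous clump if pure, else -2
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;  // atom of x ties
    bool pure = true;
    for (int t = i + 1; t < j; ++t)
      if (rows[t] != rows[i]) { pure = false; break; }
    int r0 = pure ? rows[i] : -1;
    if (pure && r0 == prev_pure_row && !clump_size.empty()) {
      clump_size.back() += j - i;
      for (int t = i; t < j; ++t) clump_rows.back()[rows[t]]++;
    } else {
      clump_size.push_back(j - i);
      clump_rows.push_back(std::vector<int>(ny, 0));
      for (int t = i; t < j; ++t) clump_rows.back()[rows[t]]++;
      prev_pure_row = pure ? r0 : -2;
    }
    if (!pure) prev_pure_row = -2;
    i = j;
  }
}

// Merge clumps down to at most k_hat superclumps (equipartition over points,
// respecting clump boundaries).
void superclumps(std::vector<int>& clump_size,
                 std::vector<std::vector<int> >& clump_rows, int ny, int k_hat) {
  int k = (int)clump_size.size();
  if (k <= k_hat) return;
  int n = 0;
  for (int t = 0; t < k; ++t) n += clump_size[t];
  std::vector<int> new_size;
  std::vector<std::vector<int> > new_rows;
  int in_sc = 0, remaining = n, left = k_hat;
  double desired = (double)remaining / left;
  for (int t = 0; t < k; ++t) {
    int m = clump_size[t];
    if (in_sc != 0 && (int)new_size.size() < k_hat &&
        std::abs(in_sc + m - desired) >= std::abs(in_sc - desired)) {
      remaining -= in_sc;
      --left;
      desired = (double)remaining / left;
      in_sc = 0;
    }
    if (in_sc == 0) {
      new_size.push_back(0);
      new_rows.push_back(std::vector<int>(ny, 0));
    }
    new_size.back() += m;
    for (int r = 0; r < ny; ++r) new_rows.back()[r] += clump_rows[t][r];
    in_sc += m;
  }
  clump_size.swap(new_size);
  clump_rows.swap(new_rows);
}

inline double xlogx(double p) { return p > 0 ? p * std::log(p) : 0.0; }

// For one orientation and one row count ny, run the DP and update mic with
// I_l / log(min(l, ny)) for every admissible column count l.
void best_for_rows(const std::vector<double>& x, const std::vector<double>& y,
                   int ny, int max_cols, int c, double& mic) {
  int n = (int)x.size();
  // order by y to equipartition rows
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return y[a] < y[b]; });
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = y[ord[i]];
  std::vector<int> row_sorted = equipartition(ys, ny);
  std::vector<int> row(n);
  for (int i = 0; i < n; ++i) row[ord[i]] = row_sorted[i];
  // order by x for clump construction
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> xs(n);
  std::vector<int> rx(n);
  for (int i = 0; i < n; ++i) { xs[i] = x[ord[i]]; rx[i] = row[ord[i]]; }

  std::vector<int> clump_size;
  std::vector<std::vector<int> > clump_rows;
  build_clumps(xs, rx, ny, clump_size, clump_rows);
  int k_hat = std::max(1, c * max_cols);
  superclumps(clump_size, clump_rows, ny, k_hat);
  int k = (int)clump_size.size();
  if (k < 2) return;

  // cumulative counts
  std::vector<double> cum(k + 1, 0.0);
  std::vector<std::vector<double> > cumR(k + 1, std::vector<double>(ny, 0.0));
  for (int t = 1; t <= k; ++t) {
    cum[t] = cum[t - 1] + clump_size[t - 1];
    for (int r = 0; r < ny; ++r)
      cumR[t][r] = cumR[t - 1][r] + clump_rows[t - 1][r];
  }
  double hq = 0.0;
  for (int r = 0; r < ny; ++r) hq -= xlogx(cumR[k][r] / n);

  // column contribution g(s, t) = sum_r (n_r / n) * log(n_r / n_col)
  auto g = [&](int s, int t) {
    double ncol = cum[t] - cum[s];
    if (ncol <= 0) return 0.0;
    double val = 0.0;
    for (int r = 0; r < ny; ++r) {
      double nr = cumR[t][r] - cumR[s][r];
      if (nr > 0) val += (nr / n) * std::log(nr / ncol);
    }
    return val;
  };

  int L = std::min(max_cols, k);
  std::vector<std::vector<double> > F(k + 1, std::vector<double>(L + 1, NEG_INF));
  for (int t = 1; t <= k; ++t) F[t][1] = g(0, t);
  for (int l = 2; l <= L; ++l) {
    for (int t = l; t <= k; ++t) {
      double best = NEG_INF;
      for (int s = l - 1; s < t; ++s) {
        if (F[s][l - 1] == NEG_INF) continue;
        double v = F[s][l - 1] + g(s, t);
        if (v > best) best = v;
      }
      F[t][l] = best;
    }
  }
  for (int l = 2; l <= L; ++l) {
    if (F[k][l] == NEG_INF) continue;
    double I = F[k][l] + hq;
    double norm = std::log((double)std::min(l, ny));
    if (norm > 0) {
      double m = I / norm;
      if (m > mic) mic = m;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
double mic_approx_cpp(NumericVector x, NumericVector y, double B, int c) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double mic = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double>& xx = orient == 0 ? xv : yv;
    const std::vector<double>& yy = orient == 0 ? yv : xv;
    for (int ny = 2; ny * 2 <= B; ++ny) {
      int max_cols = (int)std::floor(B / ny);
      if (max_cols < 2) break;
      best_for_rows(xx, yy, ny, max_cols, c, mic);
    }
  }
  if (mic > 1.0) mic = 1.0;
  if (mic < 0.0) mic = 0.0;
  return mic;
}
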