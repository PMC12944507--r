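#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Plug-in mutual information (nats) of two discrete variables given as
// small-integer codes a, b in [0, 3). Counts live on the stack; both
// variables have at most 3 levels here (3 amplitude bins / 2 classes).
static double mi_codes(const int* a, const int* b, int n) {
  double joint[9] = {0}, ma[3] = {0}, mb[3] = {0};
  for (int i = 0; i < n; ++i) {
    joint[a[i] * 3 + b[i]] += 1.0;
    ma[a[i]] += 1.0;
    mb[b[i]] += 1.0;
  }
  double mi = 0.0;
  for (int u = 0; u < 3; ++u) {
    if (ma[u] == 0.0) continue;
    for (int v = 0; v < 3; ++v) {
      const double c = joint[u * 3 + v];
      if (c == 0.0) continue;
      mi += (c / n) * std::log(c * n / (ma[u] * mb[v]));
    }
  }
  return mi < 0.0 ? 0.0 : mi;
}

// Greedy mRMR (difference form) on the rows `rows` (1-based) of X.
// Columns are discretized into 3 bins at mean +/- 0.5 sd of the subset.
// y01: class codes (0/1) aligned with `rows`. Redundancy at step t is
// sum of MI with already-selected features divided by |S|^red_exp.
// Stops at k features or when the best step score drops below min_score.
// [[Rcpp::export]]
List mrmr_greedy_cpp(NumericMatrix X, IntegerVector rows, IntegerVector y01,
                     int k, double min_score, double red_exp = 1.0) {
  const int n = rows.size();
  const int p = X.ncol();
  if (n < 2 || p == 0 || k <= 0)
    return List::create(_["selected"] = IntegerVector(0),
                        _["scores"] = NumericVector(0));

  // discretize subset columns: 3 bins at mean +/- 0.5 sd (sample sd)
  std::vector<int> d((size_t)p * n);
  std::vector<int> ridx(n);
  for (int i = 0; i < n; ++i) ridx[i] = rows[i] - 1;
  const double* xp = REAL(X);
  const int nrowX = X.nrow();
  for (int j = 0; j < p; ++j) {
    const double* col = xp + (size_t)j * nrowX;
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double v = col[ridx[i]];
      s1 += v; s2 += v * v;
    }
    const double mean = s1 / n;
    double var = (s2 - s1 * s1 / n) / (n - 1);
    if (var < 0.0) var = 0.0;
    const double half = 0.5 * std::sqrt(var);
    int* dj = &d[(size_t)j * n];
    for (int i = 0; i < n; ++i) {
      const double v = col[ridx[i]];
      dj[i] = (v < mean - half) ? 0 : (v > mean + half ? 2 : 1);
    }
  }
  std::vector<int> yv(n);
  for (int i = 0; i < n; ++i) yv[i] = y01[i];

  std::vector<double> rel(p), redsum(p, 0.0);
  for (int j = 0; j < p; ++j) rel[j] = mi_codes(&d[(size_t)j * n], yv.data(), n);

  std::vector<bool> used(p, false);
  std::vector<int> selected;
  std::vector<double> scores;
  for (int step = 0; step < k; ++step) {
    int best = -1;
    double best_score = -std::numeric_limits<double>::infinity();
    const double denom = selected.empty()
      ? 1.0 : std::pow((double)selected.size(), red_exp);
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      const double sc = selected.empty() ? rel[j] : rel[j] - redsum[j] / denom;
      if (sc > best_score) { best_score = sc; best = j; }
    }
    if (best < 0 || best_score < min_score) break;
    used[best] = true;
    selected.push_back(best + 1);
    scores.push_back(best_score);
    if ((int)selected.size() < k) {
      const int* db = &d[(size_t)best * n];
      for (int j = 0; j < p; ++j) {
        if (used[j]) continue;
        redsum[j] += mi_codes(&d[(size_t)j * n], db, n);
      }
    }
  }
  return List::create(_["selected"] = wrap(selected),
                      _["scores"] = wrap(scores));
}
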