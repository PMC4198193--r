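#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leave-one-out k-NN class-separation score of a 2-D layout.
// For each sample, the k nearest other points (Euclidean; ties broken by
// ascending sample index) vote: the sample's contribution is the fraction of
// those neighbours sharing its class. Score = 100 * mean contribution.
static double loo_knn(const std::vector<double>& px,
                      const std::vector<double>& py,
                      const IntegerVector& y, int k) {
  const int n = (int)px.size();
  // running list of the k nearest neighbours, kept sorted by (distance,
  // index); the lexicographic order is the deterministic tie rule
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int filled = 0;
    const double xi = px[i], yi = py[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - px[j], dy = yi - py[j];
      const double dd = dx * dx + dy * dy;
      if (filled == k && (dd > bd[k - 1] || (dd == bd[k - 1] && j > bi[k - 1])))
        continue;
      int t = (filled < k) ? filled : k - 1;
      while (t > 0 && (bd[t - 1] > dd || (bd[t - 1] == dd && bi[t - 1] > j))) {
        bd[t] = bd[t - 1];
        bi[t] = bi[t - 1];
        --t;
      }
      bd[t] = dd;
      bi[t] = j;
      if (filled < k) ++filled;
    }
    int same = 0;
    for (int t = 0; t < k; ++t) same += (y[bi[t]] == y[i]);
    total += (double)same / k;
  }
  return 100.0 * total / n;
}

// [[Rcpp::export]]
double score_layout_cpp(NumericVector px, NumericVector py, IntegerVector y,
                        int k) {
  int n = px.size();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n_samples");
  std::vector<double> vx(px.begin(), px.end()), vy(py.begin(), py.end());
  return loo_knn(vx, vy, y, k);
}

// Score every anchor permutation of one feature subset.
// xsub: samples x m normalized values (columns = subset features);
// orders: q x m, each row a 0-based permutation (orders(r, i) = which column
// of xsub sits at anchor i); y: 0-based class codes.
// [[Rcpp::export]]
NumericVector eval_orders_cpp(NumericMatrix xsub, IntegerMatrix orders,
                              IntegerVector y, int k) {
  const int n = xsub.nrow(), m = xsub.ncol(), q = orders.nrow();
  if (orders.ncol() != m) stop("order width must equal subset size");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n_samples");

  std::vector<double> ax(m), ay(m);
  for (int i = 0; i < m; ++i) {
    ax[i] = std::cos(2.0 * M_PI * i / m);
    ay[i] = std::sin(2.0 * M_PI * i / m);
  }
  // spring-weight sums are permutation invariant
  std::vector<double> wsum(n, 0.0);
  for (int j = 0; j < m; ++j)
    for (int s = 0; s < n; ++s) wsum[s] += xsub(s, j);

  NumericVector scores(q);
  std::vector<double> px(n), py(n);
  for (int r = 0; r < q; ++r) {
    for (int s = 0; s < n; ++s) { px[s] = 0.0; py[s] = 0.0; }
    for (int i = 0; i < m; ++i) {
      const int col = orders(r, i);
      for (int s = 0; s < n; ++s) {
        px[s] += xsub(s, col) * ax[i];
        py[s] += xsub(s, col) * ay[i];
      }
    }
    for (int s = 0; s < n; ++s) {
      if (wsum[s] > 0) { px[s] /= wsum[s]; py[s] /= wsum[s]; }
      else { px[s] = 0.0; py[s] = 0.0; }
    }
    scores[r] = loo_knn(px, py, y, k);
  }
  return scores;
}
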