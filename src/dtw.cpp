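#include <Rcpp.h>
using namespace Rcpp;

// Local cost between two scalar coordinates.
// step_cost: 0 = absolute difference, 1 = squared difference.
static inline double delta(double x, double y, int step_cost) {
  double d = x - y;
  return step_cost == 1 ? d * d : std::fabs(d);
}

// Accumulated DTW cost matrix for series a (length S) and b (length T).
// Boundary row/column are cumulative sums; interior cells take the minimum
// of the three predecessors (left, up, diagonal) plus the local cost.
// [[Rcpp::export(name = ".dtw_cost_matrix")]]
NumericMatrix dtw_cost_matrix(NumericVector a, NumericVector b, int step_cost) {
  int S = a.size(), T = b.size();
  NumericMatrix cost(S, T);
  cost(0, 0) = delta(a[0], b[0], step_cost);
  for (int i = 1; i < S; ++i) cost(i, 0) = cost(i - 1, 0) + delta(a[i], b[0], step_cost);
  for (int j = 1; j < T; ++j) cost(0, j) = cost(0, j - 1) + delta(a[0], b[j], step_cost);
  for (int i = 1; i < S; ++i) {
    for (int j = 1; j < T; ++j) {
      double up = cost(i - 1, j), left = cost(i, j - 1), diag = cost(i - 1, j - 1);
      double m = diag;
      if (left < m) m = left;
      if (up < m) m = up;
      cost(i, j) = m + delta(a[i], b[j], step_cost);
    }
  }
  return cost;
}

// DTW distance only (cost(S,T)), computed with two rolling rows.
// [[Rcpp::export(name = ".dtw_distance_cpp")]]
double dtw_distance_cpp(NumericVector a, NumericVector b, int step_cost) {
  int S = a.size(), T = b.size();
  std::vector<double> prev(T), cur(T);
  prev[0] = delta(a[0], b[0], step_cost);
  for (int j = 1; j < T; ++j) prev[j] = prev[j - 1] + delta(a[0], b[j], step_cost);
  for (int i = 1; i < S; ++i) {
    cur[0] = prev[0] + delta(a[i], b[0], step_cost);
    for (int j = 1; j < T; ++j) {
      double m = prev[j - 1];                     // diagonal
      if (cur[j - 1] < m) m = cur[j - 1];         // left
      if (prev[j] < m) m = prev[j];               // up
      cur[j] = m + delta(a[i], b[j], step_cost);
    }
    prev.swap(cur);
  }
  return prev[T - 1];
}

// Backtrack the optimal warping path from (S,T) to (1,1) through the
// accumulated cost matrix. Ties between predecessors prefer the diagonal,
// then (i, j-1), then (i-1, j). Returns a 2-column matrix of 1-based
// (i, j) pairs ordered from (1,1) to (S,T).
// [[Rcpp::export(name = ".dtw_backtrack")]]
IntegerMatrix dtw_backtrack(NumericMatrix cost) {
  int S = cost.nrow(), T = cost.ncol();
  std::vector<std::pair<int, int> > rev;
  int i = S - 1, j = T - 1;
  rev.push_back(std::make_pair(i, j));
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double diag = cost(i - 1, j - 1), left = cost(i, j - 1), up = cost(i - 1, j);
      if (diag <= left && diag <= up) { --i; --j; }
      else if (left <= up) { --j; }
      else { --i; }
    }
    rev.push_back(std::make_pair(i, j));
  }
  int L = rev.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = rev[L - 1 - k].first + 1;
    path(k, 1) = rev[L - 1 - k].second + 1;
  }
  return path;
}

// Symmetric pairwise DTW distance matrix over a list of numeric vectors.
// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(List series, int step_cost) {
  int N = series.size();
  NumericMatrix D(N, N);
  std::vector<NumericVector> xs(N);
  for (int i = 0; i < N; ++i) xs[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = dtw_distance_cpp(xs[i], xs[j], step_cost);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Rectangular cross-distance matrix: rows index `series`, columns `refs`.
// Used when scoring all objects against a small set of medoids.
// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(List series, List refs, int step_cost) {
  int N = series.size(), C = refs.size();
  NumericMatrix D(N, C);
  for (int i = 0; i < N; ++i) {
    NumericVector a = as<NumericVector>(series[i]);
    for (int c = 0; c < C; ++c) {
      NumericVector b = as<NumericVector>(refs[c]);
      D(i, c) = dtw_distance_cpp(a, b, step_cost);
    }
  }
  return D;
}
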