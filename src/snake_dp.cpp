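#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Globally optimal single-valued contour through a cost grid.
//
// States are (column, previous row, current row) so the second-difference
// rigidity term is a valid edge cost; the graph is a forward-layered DAG,
// so a column sweep of relaxations yields the same global optimum as a
// Dijkstra best-first search over the same states. Two ingredients keep it
// fast: pair image-energy terms (linear-weight vertical sweeps between
// consecutive columns) are evaluated in O(1) from per-column prefix sums
// of the cost and of row * cost, and the minimization over the predecessor
// row of dp + beta * (a - K)^2 is done for all K at once with the
// lower envelope of parabolas (the 1-D quadratic distance transform).
// max_step < 0 means unrestricted transitions.

static const double INF = std::numeric_limits<double>::infinity();

static inline double pair_energy(const std::vector<double>& S0a,
                                 const std::vector<double>& S1a,
                                 const std::vector<double>& S0b,
                                 const std::vector<double>& S1b,
                                 const double* colb, int a, int b) {
  if (a == b) return colb[b];  // documented deviation: plain cost on flat steps
  int lo = a < b ? a : b, hi = a < b ? b : a;
  double d = hi - lo;
  double s0a = S0a[hi + 1] - S0a[lo], s1a = S1a[hi + 1] - S1a[lo];
  double s0b = S0b[hi + 1] - S0b[lo], s1b = S1b[hi + 1] - S1b[lo];
  // sum_j |b - j| * Ic(prev_col, j)
  double termA = (b == hi) ? (hi * s0a - s1a) : (s1a - lo * s0a);
  // sum_j |j - a| * Ic(cur_col, j)
  double termB = (a == lo) ? (s1b - lo * s0b) : (hi * s0b - s1b);
  return (termA + termB) / (d + 1.0);
}

// lower envelope of q(a) + beta * (K - a)^2 over the parabola centres
// avals[]; queries must come with K ascending (qk ascending)
struct QuadEnvelope {
  std::vector<int> v;       // parabola centres on the envelope
  std::vector<double> z;    // breakpoints
  const double* q;
  double beta;
  int cur;
  void build(const double* q_, const std::vector<int>& avals, double beta_) {
    q = q_; beta = beta_; cur = 0;
    v.clear(); z.clear();
    for (size_t i = 0; i < avals.size(); ++i) {
      int a = avals[i];
      if (q[a] >= INF) continue;
      double s;
      while (!v.empty()) {
        int b = v.back();
        s = ((q[a] + beta * a * a) - (q[b] + beta * b * b)) /
            (2.0 * beta * (a - b));
        if (s <= z.back()) { v.pop_back(); z.pop_back(); } else break;
      }
      if (v.empty()) z.push_back(-INF); else z.push_back(s);
      v.push_back(a);
    }
    z.push_back(INF);
  }
  bool empty() const { return v.empty(); }
  // minimal value at K, with the minimizing centre in *arg
  double query(double K, int* arg) {
    while (z[cur + 1] < K) ++cur;
    int a = v[cur];
    *arg = a;
    return q[a] + beta * (K - a) * (K - a);
  }
};

// [[Rcpp::export]]
List dp_optimize_cpp(NumericMatrix cost, double alpha, double beta,
                     int row_start, int row_end, int max_step) {
  const int nr = cost.nrow(), nt = cost.ncol();
  if (nt < 2) stop("cost image needs at least 2 columns");
  if (row_start < 0 || row_start >= nr || row_end < 0 || row_end >= nr)
    stop("contour tips outside the radial range");
  const int m = (max_step < 0 || max_step >= nr) ? nr - 1 : max_step;

  // prefix sums per column: S0[c][r+1] = sum_{k<=r} cost(k,c), S1 with k*cost
  std::vector<std::vector<double> > S0(nt), S1(nt);
  for (int c = 0; c < nt; ++c) {
    S0[c].assign(nr + 1, 0.0);
    S1[c].assign(nr + 1, 0.0);
    for (int r = 0; r < nr; ++r) {
      S0[c][r + 1] = S0[c][r] + cost(r, c);
      S1[c][r + 1] = S1[c][r] + r * cost(r, c);
    }
  }

  // dp[b * nr + a]: best energy of a partial contour with f_{j-1} = a,
  // f_j = b. parent[j][c * nr + b] = the f_{j-2} achieving it.
  std::vector<double> dp((size_t)nr * nr, INF), ndp((size_t)nr * nr, INF);
  std::vector<std::vector<int> > parent(nt);

  {  // layer j = 1: f_0 fixed at row_start
    const double* col1 = &cost(0, 1);
    int a = row_start;
    for (int b = std::max(0, a - m); b <= std::min(nr - 1, a + m); ++b)
      dp[(size_t)b * nr + a] = alpha * (double)(a - b) * (a - b) +
        pair_energy(S0[0], S1[0], S0[1], S1[1], col1, a, b);
  }

  QuadEnvelope env;
  std::vector<int> avals;
  for (int j = 2; j < nt; ++j) {
    std::fill(ndp.begin(), ndp.end(), INF);
    parent[j].assign((size_t)nr * nr, -1);
    const double* colj = &cost(0, j);
    const int c_min = (j == nt - 1) ? row_end : 0;
    const int c_max = (j == nt - 1) ? row_end : nr - 1;
    for (int b = 0; b < nr; ++b) {
      const double* q = &dp[(size_t)b * nr];
      int a_lo = std::max(0, b - m), a_hi = std::min(nr - 1, b + m);
      avals.clear();
      for (int a = a_lo; a <= a_hi; ++a)
        if (q[a] < INF) avals.push_back(a);
      if (avals.empty()) continue;
      int clo = std::max(c_min, b - m), chi = std::min(c_max, b + m);
      if (clo > chi) continue;
      if (beta > 0) {
        env.build(q, avals, beta);
        // K = 2b - c is ascending as c descends
        for (int c = chi; c >= clo; --c) {
          int arg;
          double g = env.query(2.0 * b - c, &arg);
          double tot = g + alpha * (double)(b - c) * (b - c) +
            pair_energy(S0[j - 1], S1[j - 1], S0[j], S1[j], colj, b, c);
          if (tot < ndp[(size_t)c * nr + b]) {
            ndp[(size_t)c * nr + b] = tot;
            parent[j][(size_t)c * nr + b] = arg;
          }
        }
      } else {
        int arg = avals[0]; double g = q[arg];
        for (size_t i = 1; i < avals.size(); ++i)
          if (q[avals[i]] < g) { g = q[avals[i]]; arg = avals[i]; }
        for (int c = clo; c <= chi; ++c) {
          double tot = g + alpha * (double)(b - c) * (b - c) +
            pair_energy(S0[j - 1], S1[j - 1], S0[j], S1[j], colj, b, c);
          if (tot < ndp[(size_t)c * nr + b]) {
            ndp[(size_t)c * nr + b] = tot;
            parent[j][(size_t)c * nr + b] = arg;
          }
        }
      }
    }
    std::swap(dp, ndp);
  }

  IntegerVector path(nt);
  double total = INF;
  if (nt == 2) {
    total = dp[(size_t)row_end * nr + row_start];
    if (!(total < INF)) stop("no feasible contour under the step limit");
    path[0] = row_start; path[1] = row_end;
  } else {
    int best_b = -1;  // ties -> smaller previous row
    for (int b = 0; b < nr; ++b) {
      double e = dp[(size_t)row_end * nr + b];
      if (e < total) { total = e; best_b = b; }
    }
    if (best_b < 0) stop("no feasible contour under the step limit");
    path[nt - 1] = row_end;
    path[nt - 2] = best_b;
    for (int j = nt - 1; j >= 2; --j)
      path[j - 2] = parent[j][(size_t)path[j] * nr + path[j - 1]];
  }
  return List::create(_["path"] = path, _["energy"] = total);
}

// Even-odd scanline rasterization of a closed polygon at pixel centers
// (x, y) = (0..w-1, 0..h-1); pixels whose center falls on the boundary are
// included via a small epsilon on the span ends.
// [[Rcpp::export]]
IntegerMatrix rasterize_polygon_cpp(NumericVector px, NumericVector py,
                                    int h, int w) {
  const int n = px.size();
  if (n != py.size() || n < 3) stop("polygon needs at least 3 vertices");
  IntegerMatrix mask(h, w);
  const double eps = 1e-9;
  std::vector<double> xs;
  for (int y = 0; y < h; ++y) {
    xs.clear();
    for (int i = 0; i < n; ++i) {
      int k = (i + 1) % n;
      double y1 = py[i], y2 = py[k];
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        double t = (y - y1) / (y2 - y1);
        xs.push_back(px[i] + t * (px[k] - px[i]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t i = 0; i + 1 < xs.size(); i += 2) {
      int x0 = (int)std::ceil(xs[i] - eps);
      int x1 = (int)std::floor(xs[i + 1] + eps);
      if (x0 < 0) x0 = 0;
      if (x1 > w - 1) x1 = w - 1;
      for (int x = x0; x <= x1; ++x) mask(y, x) = 1;
    }
  }
  return mask;
}
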