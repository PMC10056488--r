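// 2D image primitives for polar OCT frames: bilateral filter, windowed
// standard deviation, separable Gaussian smoothing, and a first-order
// fast-marching eikonal solver with steepest-descent path extraction.
#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export(name = ".cpp_bilateral")]]
NumericMatrix cpp_bilateral(NumericMatrix img, double sigma_s, double sigma_r) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = (int)std::ceil(2.0 * sigma_s);
  NumericMatrix out(nr, nc);
  // precompute spatial kernel
  int w = 2 * rad + 1;
  std::vector<double> sk(w * w);
  for (int di = -rad; di <= rad; ++di)
    for (int dj = -rad; dj <= rad; ++dj)
      sk[(di + rad) * w + (dj + rad)] =
        std::exp(-0.5 * (di * di + dj * dj) / (sigma_s * sigma_s));
  double inv2sr2 = 0.5 / (sigma_r * sigma_r);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double c = img(i, j), num = 0.0, den = 0.0;
      for (int di = -rad; di <= rad; ++di) {
        int ii = reflect(i + di, nr);
        for (int dj = -rad; dj <= rad; ++dj) {
          int jj = reflect(j + dj, nc);
          double v = img(ii, jj);
          double d = v - c;
          double wgt = sk[(di + rad) * w + (dj + rad)] * std::exp(-d * d * inv2sr2);
          num += wgt * v;
          den += wgt;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}

// windowed standard deviation via integral images, (2*rad+1)^2 neighborhood
// [[Rcpp::export(name = ".cpp_sdfilter")]]
NumericMatrix cpp_sdfilter(NumericMatrix img, int rad) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      int n = 0;
      for (int di = -rad; di <= rad; ++di) {
        int ii = reflect(i + di, nr);
        for (int dj = -rad; dj <= rad; ++dj) {
          int jj = reflect(j + dj, nc);
          double v = img(ii, jj);
          s += v; s2 += v * v; ++n;
        }
      }
      double m = s / n;
      double var = s2 / n - m * m;
      out(i, j) = var > 0 ? std::sqrt(var) : 0.0;
    }
  }
  return out;
}

// separable Gaussian smoothing, reflective boundaries
// [[Rcpp::export(name = ".cpp_gauss2d")]]
NumericMatrix cpp_gauss2d(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0;
      for (int d = -rad; d <= rad; ++d) a += k[d + rad] * img(reflect(i + d, nr), j);
      tmp(i, j) = a;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0;
      for (int d = -rad; d <= rad; ++d) a += k[d + rad] * tmp(i, reflect(j + d, nc));
      out(i, j) = a;
    }
  return out;
}

// First-order fast marching: solves |grad T| = W from a single seed.
// W is the slowness field (>0). Returns arrival times.
// [[Rcpp::export(name = ".cpp_fmm2d")]]
NumericMatrix cpp_fmm2d(NumericMatrix W, int seed_i, int seed_j) {
  int nr = W.nrow(), nc = W.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix T(nr, nc);
  std::vector<char> frozen(nr * nc, 0);
  std::fill(T.begin(), T.end(), INF);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;
  T(seed_i, seed_j) = 0.0;
  heap.push(Node(0.0, seed_i + seed_j * nr));
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!heap.empty()) {
    Node nd = heap.top(); heap.pop();
    int idx = nd.second;
    int i = idx % nr, j = idx / nr;
    if (frozen[idx]) continue;
    frozen[idx] = 1;
    for (int q = 0; q < 4; ++q) {
      int ii = i + di[q], jj = j + dj[q];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int nidx = ii + jj * nr;
      if (frozen[nidx]) continue;
      // upwind neighbours along each axis
      double a = INF, b = INF;
      if (ii > 0) a = std::min(a, T(ii - 1, jj));
      if (ii < nr - 1) a = std::min(a, T(ii + 1, jj));
      if (jj > 0) b = std::min(b, T(ii, jj - 1));
      if (jj < nc - 1) b = std::min(b, T(ii, jj + 1));
      double w = W(ii, jj);
      double tnew;
      double lo = std::min(a, b), hi = std::max(a, b);
      if (hi == INF || hi - lo >= w) {
        tnew = lo + w;
      } else {
        double sum = a + b;
        double disc = 2.0 * w * w - (a - b) * (a - b);
        tnew = 0.5 * (sum + std::sqrt(disc));
      }
      if (tnew < T(ii, jj)) {
        T(ii, jj) = tnew;
        heap.push(Node(tnew, nidx));
      }
    }
  }
  return T;
}

// Discrete steepest descent on an arrival-time map from (end_i, end_j)
// back to the zero-time seed. Returns a 2-column matrix of 0-based (i, j).
// [[Rcpp::export(name = ".cpp_descend")]]
IntegerMatrix cpp_descend(NumericMatrix T, int end_i, int end_j) {
  int nr = T.nrow(), nc = T.ncol();
  std::vector<int> ri, rj;
  int i = end_i, j = end_j;
  int maxsteps = 4 * (nr + nc) + nr * 4;
  for (int s = 0; s < maxsteps; ++s) {
    ri.push_back(i); rj.push_back(j);
    if (T(i, j) <= 0) break;
    double best = T(i, j);
    int bi = i, bj = j;
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (T(ii, jj) < best) { best = T(ii, jj); bi = ii; bj = jj; }
      }
    if (bi == i && bj == j) break; // local minimum (seed)
    i = bi; j = bj;
  }
  int n = ri.size();
  IntegerMatrix out(n, 2);
  for (int q = 0; q < n; ++q) { out(q, 0) = ri[q]; out(q, 1) = rj[q]; }
  return out;
}
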