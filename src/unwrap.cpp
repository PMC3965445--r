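#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quality-guided 2D phase unwrapping (flood fill from the highest-quality
// pixel, growing the unwrapped region through a max-heap of border pixels).
// Quality is the negative local variance of wrapped phase differences, so
// smooth regions are unwrapped first and noisy pixels last. `period` is the
// congruence modulus (2*pi for ordinary phase images, pi for half-scaled
// phase-difference images).

static inline double wrapd(double x, double period) {
  double half = period / 2.0;
  double r = (x + half) / period;
  return (r - std::floor(r)) * period - half;
}

struct QPix {
  double q;
  int idx;
  int from;
  bool operator<(const QPix& other) const { return q < other.q; }
};

// [[Rcpp::export(name = ".unwrap_quality_cpp")]]
NumericMatrix unwrap_quality_cpp(NumericMatrix wrapped, double period) {
  int nr = wrapped.nrow(), nc = wrapped.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  std::vector<bool> done(n, false);
  std::vector<double> quality(n);

  // local quality: negative variance of wrapped first differences in a
  // 3x3 neighbourhood
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      int m = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (di == 0 && dj == 0) continue;
          double d = wrapd(wrapped(ii, jj) - wrapped(i, j), period);
          s += d; s2 += d * d; ++m;
        }
      }
      double var = (m > 0) ? (s2 / m - (s / m) * (s / m)) : 0.0;
      quality[i + j * nr] = -var;
    }
  }

  int seed = 0;
  for (int k = 1; k < n; ++k) if (quality[k] > quality[seed]) seed = k;

  std::priority_queue<QPix> heap;
  out[seed] = wrapped[seed];
  done[seed] = true;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  auto push_neighbours = [&](int idx) {
    int i = idx % nr, j = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int nb = ii + jj * nr;
      if (!done[nb]) heap.push({quality[nb], nb, idx});
    }
  };
  push_neighbours(seed);

  while (!heap.empty()) {
    QPix p = heap.top();
    heap.pop();
    if (done[p.idx]) continue;
    double step = wrapd(wrapped[p.idx] - wrapped[p.from], period);
    out[p.idx] = out[p.from] + step;
    done[p.idx] = true;
    push_neighbours(p.idx);
  }
  return out;
}
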