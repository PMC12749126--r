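#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Quality-guided 2D phase unwrapping by region growing.
//
// Pixels are visited in order of a local smoothness quality (negative sum of
// squared wrapped second differences); each new pixel's unwrapped value is the
// unwrapping of its wrapped value against an already-unwrapped neighbour.
// Adds only integer multiples of 2*pi, so congruence with the input modulo
// 2*pi holds exactly. Each connected component of the mask is seeded at its
// highest-quality pixel; components carry independent 2*pi*n constants.

// wrap to (-pi, pi]; avoids std::fmod (its versioned libm symbol is newer
// than some runtime glibc builds paired with the conda toolchain)
static inline double wrap_pm_pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  return x - TWO_PI * std::ceil((x - M_PI) / TWO_PI);
}

struct QPix {
  double q;
  int idx;
  bool operator<(const QPix& o) const { return q < o.q; }
};

// [[Rcpp::export(name = ".unwrap2d_cpp")]]
NumericMatrix unwrap2d_cpp(NumericMatrix wrapped, LogicalMatrix mask) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("mask dimensions must match the phase image");

  NumericMatrix out(nr, nc);
  std::vector<char> visited(nr * nc, 0);
  std::vector<double> quality(nr * nc, 0.0);

  auto at = [nr](int i, int j) { return i + nr * j; };

  // local quality: negative energy of wrapped second differences
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { quality[at(i, j)] = -1e300; continue; }
      double q = 0.0;
      if (i > 0 && i < nr - 1 && mask(i - 1, j) && mask(i + 1, j)) {
        double d = wrap_pm_pi(wrapped(i - 1, j) - wrapped(i, j)) -
                   wrap_pm_pi(wrapped(i, j) - wrapped(i + 1, j));
        q -= d * d;
      }
      if (j > 0 && j < nc - 1 && mask(i, j - 1) && mask(i, j + 1)) {
        double d = wrap_pm_pi(wrapped(i, j - 1) - wrapped(i, j)) -
                   wrap_pm_pi(wrapped(i, j) - wrapped(i, j + 1));
        q -= d * d;
      }
      quality[at(i, j)] = q;
    }
  }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  std::priority_queue<QPix> heap;
  int n_masked = 0, n_done = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) ++n_masked;

  while (n_done < n_masked) {
    // seed: best-quality unvisited masked pixel
    int seed = -1; double best = -1e301;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int id = at(i, j);
        if (mask(i, j) && !visited[id] && quality[id] > best) {
          best = quality[id]; seed = id;
        }
      }
    if (seed < 0) break;
    int si = seed % nr, sj = seed / nr;
    out(si, sj) = wrapped(si, sj);
    visited[seed] = 1; ++n_done;
    heap.push({quality[seed], seed});

    while (!heap.empty()) {
      QPix p = heap.top(); heap.pop();
      int pi = p.idx % nr, pj = p.idx / nr;
      for (int t = 0; t < 4; ++t) {
        int ni = pi + di[t], nj = pj + dj[t];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int nid = at(ni, nj);
        if (!mask(ni, nj) || visited[nid]) continue;
        out(ni, nj) = out(pi, pj) +
                      wrap_pm_pi(wrapped(ni, nj) - wrapped(pi, pj));
        visited[nid] = 1; ++n_done;
        heap.push({quality[nid], nid});
      }
    }
  }

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (!mask(i, j)) out(i, j) = NA_REAL;

  return out;
}
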