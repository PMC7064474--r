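// Binary and grayscale morphology primitives for nuclei segmentation.
//
// Image convention: R numeric/integer matrices, rows = y (top to bottom),
// cols = x.  Binary masks are integer matrices with values in {0, 1}.
// Outside-of-image pixels are treated as background for binary erosion
// (objects shrink inward at borders) and as -Inf for grayscale dilation.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- erosion

// [[Rcpp::export]]
IntegerMatrix cpp_binary_erode(const IntegerMatrix& mask,
                               const IntegerMatrix& se) {
  const int H = mask.nrow(), W = mask.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  if (sh % 2 == 0 || sw % 2 == 0)
    stop("structuring element must have odd side lengths");
  const int cy = sh / 2, cx = sw / 2;

  // collect SE offsets once
  std::vector<int> dy, dx;
  for (int j = 0; j < sw; ++j)
    for (int i = 0; i < sh; ++i)
      if (se(i, j) != 0) { dy.push_back(i - cy); dx.push_back(j - cx); }
  const int n = (int)dy.size();
  if (n == 0) stop("structuring element is empty");

  IntegerMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x)) { out(y, x) = 0; continue; }
      int keep = 1;
      for (int k = 0; k < n; ++k) {
        const int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W || !mask(yy, xx)) {
          keep = 0; break;
        }
      }
      out(y, x) = keep;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_binary_dilate(const IntegerMatrix& mask,
                                const IntegerMatrix& se) {
  const int H = mask.nrow(), W = mask.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  if (sh % 2 == 0 || sw % 2 == 0)
    stop("structuring element must have odd side lengths");
  const int cy = sh / 2, cx = sw / 2;
  IntegerMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x)) continue;
      for (int j = 0; j < sw; ++j)
        for (int i = 0; i < sh; ++i) {
          if (!se(i, j)) continue;
          // reflected SE for dilation; symmetric SEs make this moot
          const int yy = y - (i - cy), xx = x - (j - cx);
          if (yy >= 0 && yy < H && xx >= 0 && xx < W) out(yy, xx) = 1;
        }
    }
  return out;
}

// ----------------------------------------------------- connected components

// Labels maximal connected components 1..N in raster-scan order (row by
// row, left to right within a row) of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask,
                                   const int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      lab(y, x) = next;
      stack.clear();
      stack.push_back(y + x * H);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int py = p % H, px = p / H;
        for (int k = 0; k < nn; ++k) {
          const int yy = py + dy8[k], xx = px + dx8[k];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          if (mask(yy, xx) && !lab(yy, xx)) {
            lab(yy, xx) = next;
            stack.push_back(yy + xx * H);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// ------------------------------------------------ Euclidean distance map

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas); exact.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance from each foreground pixel to the nearest
// background pixel centre; 0 on background.
// [[Rcpp::export]]
NumericMatrix cpp_distance_map(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(H, W);
  // columns first
  {
    std::vector<double> f(H), d(H), z(H + 1);
    std::vector<int> v(H);
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) f[y] = mask(y, x) ? INF : 0.0;
      dt1d(f, d, v, z);
      for (int y = 0; y < H; ++y) g(y, x) = d[y];
    }
  }
  // then rows
  {
    std::vector<double> f(W), d(W), z(W + 1);
    std::vector<int> v(W);
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) f[x] = g(y, x);
      dt1d(f, d, v, z);
      for (int x = 0; x < W; ++x) g(y, x) = std::sqrt(d[x]);
    }
  }
  return g;
}

// ----------------------------------------- grayscale geodesic reconstruction

// One elementary geodesic dilation: min(dilate(marker, cross), mask).
// The elementary SE is the 4-connected cross including the centre.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_dilate(const NumericMatrix& marker,
                                  const NumericMatrix& mask) {
  const int H = marker.nrow(), W = marker.ncol();
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double m = marker(y, x);
      if (y > 0)     m = std::max(m, marker(y - 1, x));
      if (y < H - 1) m = std::max(m, marker(y + 1, x));
      if (x > 0)     m = std::max(m, marker(y, x - 1));
      if (x < W - 1) m = std::max(m, marker(y, x + 1));
      out(y, x) = std::min(m, mask(y, x));
    }
  return out;
}

// Morphological reconstruction by dilation (limit of iterated elementary
// geodesic dilations), 4-connected; hybrid raster/anti-raster sweep with a
// FIFO queue (Vincent 1993).  Exact fixpoint.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(const NumericMatrix& marker,
                              const NumericMatrix& mask) {
  const int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("shape mismatch");
  NumericMatrix J(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (marker(y, x) > mask(y, x) + 1e-12)
        stop("marker must be <= mask everywhere");
      J(y, x) = marker(y, x);
    }

  // forward raster sweep: neighbours N+ = {up, left}
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double m = J(y, x);
      if (y > 0) m = std::max(m, J(y - 1, x));
      if (x > 0) m = std::max(m, J(y, x - 1));
      J(y, x) = std::min(m, mask(y, x));
    }
  // backward sweep: N- = {down, right}; enqueue frontier pixels
  std::queue<int> fifo;
  for (int y = H - 1; y >= 0; --y)
    for (int x = W - 1; x >= 0; --x) {
      double m = J(y, x);
      if (y < H - 1) m = std::max(m, J(y + 1, x));
      if (x < W - 1) m = std::max(m, J(y, x + 1));
      J(y, x) = std::min(m, mask(y, x));
      const double jc = J(y, x);
      bool push = false;
      if (y < H - 1 && J(y + 1, x) < jc && J(y + 1, x) < mask(y + 1, x))
        push = true;
      if (!push && x < W - 1 && J(y, x + 1) < jc && J(y, x + 1) < mask(y, x + 1))
        push = true;
      if (push) fifo.push(y + x * H);
    }
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    const int p = fifo.front(); fifo.pop();
    const int py = p % H, px = p / H;
    const double jp = J(py, px);
    for (int k = 0; k < 4; ++k) {
      const int yy = py + dy[k], xx = px + dx[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (J(yy, xx) < jp && J(yy, xx) < mask(yy, xx)) {
        J(yy, xx) = std::min(jp, mask(yy, xx));
        fifo.push(yy + xx * H);
      }
    }
  }
  return J;
}

// ------------------------------------------------------- regional maxima

// Labels regional maxima (connected plateaus with no strictly higher
// neighbour) of img restricted to mask.  Plateau connectivity 8.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(const NumericMatrix& img,
                                  const IntegerMatrix& mask) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);   // 0 unvisited; -1 visited non-max; >0 max label
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> plateau, stack;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      const double v = img(y, x);
      bool is_max = true;
      plateau.clear(); stack.clear();
      stack.push_back(y + x * H);
      lab(y, x) = -2;  // mark as in current plateau
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        const int py = p % H, px = p / H;
        for (int k = 0; k < 8; ++k) {
          const int yy = py + dy8[k], xx = px + dx8[k];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          if (!mask(yy, xx)) continue;  // background never disqualifies
          const double w = img(yy, xx);
          if (w > v) is_max = false;
          else if (w == v && lab(yy, xx) == 0) {
            lab(yy, xx) = -2;
            stack.push_back(yy + xx * H);
          }
        }
      }
      const int tag = is_max ? ++next : -1;
      for (size_t i = 0; i < plateau.size(); ++i)
        lab(plateau[i] % H, plateau[i] / H) = tag;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (lab(y, x) < 0) lab(y, x) = 0;
  lab.attr("n") = next;
  return lab;
}

// ------------------------------------------------------ seeded watershed

struct QItem {
  double prio;
  unsigned long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // min-heap on priority
    return a.order > b.order;                       // FIFO on ties
  }
};

// Priority-flood watershed (Meyer): basins grow from labelled seeds in
// increasing order of `height` (pass the negated topographic map so that
// basins sit at its maxima), restricted to mask, 4-connected.  Every mask
// pixel reachable from a seed is assigned to exactly one basin;
// watershed-line pixels go to the first-arriving basin.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& height,
                            const IntegerMatrix& seeds,
                            const IntegerMatrix& mask) {
  const int H = height.nrow(), W = height.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long order = 0;
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};

  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (seeds(y, x) > 0 && mask(y, x)) {
        lab(y, x) = seeds(y, x);
        pq.push({height(y, x), order++, y + x * H});
      }

  while (!pq.empty()) {
    const QItem it = pq.top(); pq.pop();
    const int py = it.idx % H, px = it.idx / H;
    const int l = lab(py, px);
    for (int k = 0; k < 4; ++k) {
      const int yy = py + dy[k], xx = px + dx[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (!mask(yy, xx) || lab(yy, xx)) continue;
      lab(yy, xx) = l;
      pq.push({height(yy, xx), order++, yy + xx * H});
    }
  }
  return lab;
}

// ------------------------------------------------------------- Hausdorff

// Exact Hausdorff distance between two pixel coordinate sets (n x 2
// matrices), Euclidean metric, with early-exit inner loops.
// [[Rcpp::export]]
double cpp_hausdorff(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("empty point set");
  double h = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix& P = pass == 0 ? a : b;
    const NumericMatrix& Q = pass == 0 ? b : a;
    const int np = P.nrow(), nq = Q.nrow();
    for (int i = 0; i < np; ++i) {
      double best = std::numeric_limits<double>::infinity();
      const double py = P(i, 0), px = P(i, 1);
      for (int j = 0; j < nq; ++j) {
        const double dyv = py - Q(j, 0), dxv = px - Q(j, 1);
        const double d2 = dyv * dyv + dxv * dxv;
        if (d2 < best) {
          best = d2;
          if (best <= h * h) break;  // cannot raise the running max
        }
      }
      if (best > h * h) h = std::sqrt(best);
    }
  }
  return h;
}

// ------------------------------------------------------- patch utilities

static inline int reflect_idx(int i, int n) {
  // reflect without repeating the border pixel (like scipy 'reflect'/
  // numpy 'symmetric' for the first period); n >= 1
  if (n == 1) return 0;
  const int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - 1 - i;
}

// Extracts size x size patches centred at 1-based (y, x) coordinates with
// reflection padding; returns N x size^2 matrix (patch values column-major
// within the patch frame).
// [[Rcpp::export]]
NumericMatrix cpp_extract_patches(const NumericMatrix& img,
                                  const IntegerMatrix& centers,
                                  const int size) {
  if (size % 2 == 0) stop("patch size must be odd");
  const int H = img.nrow(), W = img.ncol();
  const int r = size / 2, n = centers.nrow();
  NumericMatrix out(n, size * size);
  for (int i = 0; i < n; ++i) {
    const int cy = centers(i, 0) - 1, cx = centers(i, 1) - 1;
    int k = 0;
    for (int dx = -r; dx <= r; ++dx) {
      const int xx = reflect_idx(cx + dx, W);
      for (int dy = -r; dy <= r; ++dy) {
        const int yy = reflect_idx(cy + dy, H);
        out(i, k++) = img(yy, xx);
      }
    }
  }
  return out;
}

// Local mean over a (2r+1) square window via integral image; window is
// clipped at image borders (mean over the valid part).
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& img, const int r) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<double> S((H + 1) * (W + 1), 0.0);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      S[(y + 1) + (x + 1) * (H + 1)] =
        img(y, x) + S[y + (x + 1) * (H + 1)] + S[(y + 1) + x * (H + 1)] -
        S[y + x * (H + 1)];
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      const int y0 = std::max(0, y - r), y1 = std::min(H - 1, y + r);
      const int x0 = std::max(0, x - r), x1 = std::min(W - 1, x + r);
      const double s = S[(y1 + 1) + (x1 + 1) * (H + 1)] -
                       S[y0 + (x1 + 1) * (H + 1)] -
                       S[(y1 + 1) + x0 * (H + 1)] + S[y0 + x0 * (H + 1)];
      out(y, x) = s / ((y1 - y0 + 1) * (double)(x1 - x0 + 1));
    }
  return out;
}
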