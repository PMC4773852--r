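#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

// symmetric (reflective, edge-repeating) boundary index
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Local sum over a disc neighbourhood of radius r (pixels at Euclidean
// distance <= r from the centre), reflective padding.  Matrix layout is
// [x, y] column-major, matching EBImage.
// [[Rcpp::export]]
NumericMatrix cpp_disc_local_sum(const NumericMatrix& X, int r) {
  const int nx = X.nrow(), ny = X.ncol();
  std::vector<int> wx(2 * r + 1);
  for (int dy = -r; dy <= r; ++dy)
    wx[dy + r] = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy) + 1e-9);

  const int px = nx + 2 * r, py = ny + 2 * r;
  // padded column-wise cumulative sums along x: C has px+1 rows
  std::vector<double> C((size_t)(px + 1) * py);
  for (int y = 0; y < py; ++y) {
    const int ys = refl(y - r, ny);
    double acc = 0.0;
    double* col = &C[(size_t)y * (px + 1)];
    col[0] = 0.0;
    for (int x = 0; x < px; ++x) {
      acc += X(refl(x - r, nx), ys);
      col[x + 1] = acc;
    }
  }

  NumericMatrix S(nx, ny);
  for (int y = 0; y < ny; ++y) {
    for (int dy = -r; dy <= r; ++dy) {
      const int w = wx[dy + r];
      const double* col = &C[(size_t)(y + r + dy) * (px + 1)];
      double* out = &S(0, y);
      for (int x = 0; x < nx; ++x) {
        const int xc = x + r;                 // position in padded coords
        out[x] += col[xc + w + 1] - col[xc - w];
      }
    }
  }
  return S;
}

// Number of pixels in the disc of radius r (window area; constant under
// reflective padding).
// [[Rcpp::export]]
int cpp_disc_area(int r) {
  int a = 0;
  for (int dy = -r; dy <= r; ++dy) {
    int w = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy) + 1e-9);
    a += 2 * w + 1;
  }
  return a;
}

// 8-connected component labeling by union-find, two passes.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& M) {
  const int nx = M.nrow(), ny = M.ncol();
  IntegerMatrix L(nx, ny);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      if (!M(x, y)) continue;
      int best = 0;
      // previously-scanned 8-neighbours: (x-1,y), (x-1,y-1), (x,y-1), (x+1,y-1)
      const int cand[4][2] = {{x - 1, y}, {x - 1, y - 1}, {x, y - 1}, {x + 1, y - 1}};
      for (int k = 0; k < 4; ++k) {
        const int cx = cand[k][0], cy = cand[k][1];
        if (cx < 0 || cx >= nx || cy < 0) continue;
        const int l = L(cx, cy);
        if (l > 0) {
          if (best == 0) best = l; else unite(best, l);
        }
      }
      if (best == 0) {
        best = (int)parent.size();
        parent.push_back(best);
      }
      L(x, y) = best;
    }
  }

  // relabel consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      if (L(x, y) > 0) {
        int root = find(L(x, y));
        if (remap[root] == 0) remap[root] = ++next;
        L(x, y) = remap[root];
      }
  return L;
}

// Accumulate anti-aliased line segments into an image.  Coordinates are
// 0-based pixel centres; intensity falls off linearly from `amp` inside the
// half-thickness to 0 one pixel outside it.
// [[Rcpp::export]]
NumericMatrix cpp_draw_segments(int nx, int ny,
                                const NumericVector& x0, const NumericVector& y0,
                                const NumericVector& x1, const NumericVector& y1,
                                const NumericVector& amp, double half_thickness) {
  NumericMatrix img(nx, ny);
  const int n = x0.size();
  const double reach = half_thickness + 1.0;
  for (int i = 0; i < n; ++i) {
    const double ax = x0[i], ay = y0[i], bx = x1[i], by = y1[i];
    const double vx = bx - ax, vy = by - ay;
    const double len2 = vx * vx + vy * vy;
    const int xmin = std::max(0, (int)std::floor(std::min(ax, bx) - reach));
    const int xmax = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + reach));
    const int ymin = std::max(0, (int)std::floor(std::min(ay, by) - reach));
    const int ymax = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + reach));
    for (int y = ymin; y <= ymax; ++y) {
      for (int x = xmin; x <= xmax; ++x) {
        double t = 0.0;
        if (len2 > 0.0)
          t = std::max(0.0, std::min(1.0, ((x - ax) * vx + (y - ay) * vy) / len2));
        const double dx = x - (ax + t * vx), dy = y - (ay + t * vy);
        const double d = std::sqrt(dx * dx + dy * dy);
        const double w = std::max(0.0, std::min(1.0, half_thickness + 0.5 - d));
        if (w > 0.0) img(x, y) += amp[i] * w;
      }
    }
  }
  return img;
}
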