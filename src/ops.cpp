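#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are stored as C x (N*H*W) matrices. Column index for pixel
// (x, y) of sample n (all 0-based) is (n*H + y)*W + x, i.e. x fastest.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int C, int H, int W, int N,
                         int k, int stride, int pad, int dil) {
  const int Ho = (H + 2 * pad - (dil * (k - 1) + 1)) / stride + 1;
  const int Wo = (W + 2 * pad - (dil * (k - 1) + 1)) / stride + 1;
  NumericMatrix P(C * k * k, N * Ho * Wo);
  const double* x = X.begin();
  double* p = P.begin();
  const int prow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const int ocol = (n * Ho + oy) * Wo + ox;
        double* pc = p + (size_t)ocol * prow;
        for (int c = 0; c < C; ++c) {
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky * dil;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx * dil;
              double v = 0.0;
              if (iy >= 0 && iy < H && ix >= 0 && ix < W) {
                const int icol = (n * H + iy) * W + ix;
                v = x[c + (size_t)icol * C];
              }
              pc[c * k * k + ky * k + kx] = v;
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& P, int C, int H, int W, int N,
                         int k, int stride, int pad, int dil) {
  const int Ho = (H + 2 * pad - (dil * (k - 1) + 1)) / stride + 1;
  const int Wo = (W + 2 * pad - (dil * (k - 1) + 1)) / stride + 1;
  NumericMatrix X(C, N * H * W);
  const double* p = P.begin();
  double* x = X.begin();
  const int prow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const int ocol = (n * Ho + oy) * Wo + ox;
        const double* pc = p + (size_t)ocol * prow;
        for (int c = 0; c < C; ++c) {
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky * dil;
            if (iy < 0 || iy >= H) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx * dil;
              if (ix < 0 || ix >= W) continue;
              const int icol = (n * H + iy) * W + ix;
              x[c + (size_t)icol * C] += pc[c * k * k + ky * k + kx];
            }
          }
        }
      }
    }
  }
  return X;
}

// CARAFE content-aware reassembly. K holds one normalized kup*kup kernel per
// output position (rows indexed ky*kup+kx); every channel at a position
// shares that kernel. Source position is floor(output/sigma); the kup x kup
// neighborhood around it is combined with zero padding at borders.
// [[Rcpp::export]]
NumericMatrix cpp_carafe_forward(const NumericMatrix& X, const NumericMatrix& K,
                                 int C, int H, int W, int N, int sigma, int kup) {
  const int Ho = H * sigma, Wo = W * sigma, rad = (kup - 1) / 2;
  NumericMatrix Y(C, N * Ho * Wo);
  const double* x = X.begin();
  const double* kk = K.begin();
  double* y = Y.begin();
  const int krow = kup * kup;
  for (int n = 0; n < N; ++n) {
    for (int oy = 0; oy < Ho; ++oy) {
      const int sy = oy / sigma;
      for (int ox = 0; ox < Wo; ++ox) {
        const int sx = ox / sigma;
        const int ocol = (n * Ho + oy) * Wo + ox;
        const double* kc = kk + (size_t)ocol * krow;
        double* yc = y + (size_t)ocol * C;
        for (int ky = 0; ky < kup; ++ky) {
          const int iy = sy + ky - rad;
          if (iy < 0 || iy >= H) continue;
          for (int kx = 0; kx < kup; ++kx) {
            const int ix = sx + kx - rad;
            if (ix < 0 || ix >= W) continue;
            const double wgt = kc[ky * kup + kx];
            if (wgt == 0.0) continue;
            const double* xc = x + (size_t)((n * H + iy) * W + ix) * C;
            for (int c = 0; c < C; ++c) yc[c] += wgt * xc[c];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_carafe_backward(const NumericMatrix& GY, const NumericMatrix& X,
                         const NumericMatrix& K, int C, int H, int W, int N,
                         int sigma, int kup) {
  const int Ho = H * sigma, Wo = W * sigma, rad = (kup - 1) / 2;
  NumericMatrix GX(C, N * H * W);
  NumericMatrix GK(kup * kup, N * Ho * Wo);
  const double* gy = GY.begin();
  const double* x = X.begin();
  const double* kk = K.begin();
  double* gx = GX.begin();
  double* gk = GK.begin();
  const int krow = kup * kup;
  for (int n = 0; n < N; ++n) {
    for (int oy = 0; oy < Ho; ++oy) {
      const int sy = oy / sigma;
      for (int ox = 0; ox < Wo; ++ox) {
        const int sx = ox / sigma;
        const int ocol = (n * Ho + oy) * Wo + ox;
        const double* kc = kk + (size_t)ocol * krow;
        const double* gyc = gy + (size_t)ocol * C;
        double* gkc = gk + (size_t)ocol * krow;
        for (int ky = 0; ky < kup; ++ky) {
          const int iy = sy + ky - rad;
          if (iy < 0 || iy >= H) continue;
          for (int kx = 0; kx < kup; ++kx) {
            const int ix = sx + kx - rad;
            if (ix < 0 || ix >= W) continue;
            const size_t icol = (size_t)((n * H + iy) * W + ix);
            const double* xc = x + icol * C;
            double* gxc = gx + icol * C;
            const double wgt = kc[ky * kup + kx];
            double acc = 0.0;
            for (int c = 0; c < C; ++c) {
              acc += gyc[c] * xc[c];
              gxc[c] += wgt * gyc[c];
            }
            gkc[ky * kup + kx] = acc;
          }
        }
      }
    }
  }
  return List::create(Named("gx") = GX, Named("gk") = GK);
}

// 8-connected component labelling of a binary H x W image (x-fastest layout).
// [[Rcpp::export]]
IntegerVector cpp_label_components(const IntegerVector& mask, int H, int W) {
  IntegerVector lab(H * W, 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < H * W; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      const int idx = q.front(); q.pop();
      const int y = idx / W, x = idx % W;
      for (int dy = -1; dy <= 1; ++dy) {
        const int ny = y + dy;
        if (ny < 0 || ny >= H) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int nx = x + dx;
          if (nx < 0 || nx >= W) continue;
          const int nidx = ny * W + nx;
          if (mask[nidx] != 0 && lab[nidx] == 0) {
            lab[nidx] = next;
            q.push(nidx);
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb(const std::vector<int>& b, int H, int W, int y, int x) {
  if (y < 0 || y >= H || x < 0 || x >= W) return 0;
  return b[y * W + x];
}

// Number of 0->1 transitions in the circular sequence p2,p3,...,p9,p2
// (neighbors clockwise from north).
static int crossing_number(const std::vector<int>& b, int H, int W, int y, int x) {
  const int p[8] = {
    nb(b, H, W, y - 1, x),     nb(b, H, W, y - 1, x + 1),
    nb(b, H, W, y, x + 1),     nb(b, H, W, y + 1, x + 1),
    nb(b, H, W, y + 1, x),     nb(b, H, W, y + 1, x - 1),
    nb(b, H, W, y, x - 1),     nb(b, H, W, y - 1, x - 1)};
  int a = 0;
  for (int i = 0; i < 8; ++i)
    if (p[i] == 0 && p[(i + 1) % 8] == 1) ++a;
  return a;
}

// True when the two foreground neighbors are 8-adjacent to each other: the
// pixel is the terminal corner of a 1-px staircase line. Deleting such
// pixels would retract slanted line ends one pixel per pass.
static bool staircase_end(const std::vector<int>& b, int H, int W, int y, int x) {
  const int p[8] = {
    nb(b, H, W, y - 1, x),     nb(b, H, W, y - 1, x + 1),
    nb(b, H, W, y, x + 1),     nb(b, H, W, y + 1, x + 1),
    nb(b, H, W, y + 1, x),     nb(b, H, W, y + 1, x - 1),
    nb(b, H, W, y, x - 1),     nb(b, H, W, y - 1, x - 1)};
  int first = -1, second = -1, cnt = 0;
  for (int i = 0; i < 8; ++i) {
    if (p[i]) {
      if (cnt == 0) first = i; else second = i;
      ++cnt;
    }
  }
  if (cnt != 2) return false;
  const int d = second - first;
  return d == 1 || d == 7;
}

// Hilditch thinning: per pass, mark boundary pixels whose deletion keeps the
// skeleton connected (neighbor count in [2,6], exactly one 0->1 transition in
// the 8-neighborhood cycle, the two connectivity-preservation tests on the
// north and east neighbors, and not a staircase line end), then delete;
// repeat to a fixed point.
// [[Rcpp::export]]
IntegerVector cpp_hilditch(const IntegerVector& mask, int H, int W, int maxiter) {
  std::vector<int> b(mask.begin(), mask.end());
  std::vector<int> del(H * W, 0);
  for (int it = 0; it < maxiter; ++it) {
    int ndel = 0;
    std::fill(del.begin(), del.end(), 0);
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        if (!b[y * W + x]) continue;
        const int p2 = nb(b, H, W, y - 1, x);
        const int p4 = nb(b, H, W, y, x + 1);
        const int p6 = nb(b, H, W, y + 1, x);
        const int p8 = nb(b, H, W, y, x - 1);
        const int B = p2 + p4 + p6 + p8 + nb(b, H, W, y - 1, x + 1) +
                      nb(b, H, W, y + 1, x + 1) + nb(b, H, W, y + 1, x - 1) +
                      nb(b, H, W, y - 1, x - 1);
        if (B < 2 || B > 6) continue;
        if (staircase_end(b, H, W, y, x)) continue;
        if (crossing_number(b, H, W, y, x) != 1) continue;
        if (p2 * p4 * p8 != 0 && crossing_number(b, H, W, y - 1, x) == 1) continue;
        if (p2 * p4 * p6 != 0 && crossing_number(b, H, W, y, x + 1) == 1) continue;
        del[y * W + x] = 1;
        ++ndel;
      }
    }
    if (ndel == 0) break;
    for (int i = 0; i < H * W; ++i) {
      if (del[i]) b[i] = 0;
    }
  }
  // Final cleanup: the staircase-end protection can leave fully occupied
  // 2x2 blocks at junctions; peel removable (simple, non-endpoint) pixels
  // of such blocks until none remain.
  bool changed = true;
  while (changed) {
    changed = false;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        if (!b[y * W + x]) continue;
        bool inblock = false;
        for (int dy = -1; dy <= 0 && !inblock; ++dy) {
          for (int dx = -1; dx <= 0 && !inblock; ++dx) {
            if (nb(b, H, W, y + dy, x + dx) && nb(b, H, W, y + dy, x + dx + 1) &&
                nb(b, H, W, y + dy + 1, x + dx) && nb(b, H, W, y + dy + 1, x + dx + 1))
              inblock = true;
          }
        }
        if (!inblock) continue;
        const int B = nb(b, H, W, y - 1, x) + nb(b, H, W, y, x + 1) +
                      nb(b, H, W, y + 1, x) + nb(b, H, W, y, x - 1) +
                      nb(b, H, W, y - 1, x + 1) + nb(b, H, W, y + 1, x + 1) +
                      nb(b, H, W, y + 1, x - 1) + nb(b, H, W, y - 1, x - 1);
        if (B < 2) continue;
        if (crossing_number(b, H, W, y, x) != 1) continue;
        b[y * W + x] = 0;
        changed = true;
      }
    }
  }
  return IntegerVector(b.begin(), b.end());
}

// Even-odd scan-line polygon fill; vertices in image (x, y) convention,
// pixel centers at integer coordinates. Returns a logical H x W mask
// (x-fastest layout, consistent with the rest of the package).
// [[Rcpp::export]]
LogicalVector cpp_fill_polygon(const NumericVector& xs, const NumericVector& ys,
                               int H, int W) {
  LogicalVector out(H * W, false);
  const int nv = xs.size();
  std::vector<double> cross;
  for (int row = 0; row < H; ++row) {
    const double y = (double)row;
    cross.clear();
    for (int i = 0; i < nv; ++i) {
      const int j = (i + 1) % nv;
      const double y1 = ys[i], y2 = ys[j];
      if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
        cross.push_back(xs[i] + (y - y1) * (xs[j] - xs[i]) / (y2 - y1));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (size_t i = 0; i + 1 < cross.size(); i += 2) {
      int x0 = (int)std::ceil(cross[i] - 1e-9);
      int x1 = (int)std::floor(cross[i + 1] - 1e-9);
      if (x0 < 0) x0 = 0;
      if (x1 >= W) x1 = W - 1;
      for (int x = x0; x <= x1; ++x) out[row * W + x] = true;
    }
  }
  return out;
}

// Hough-gradient circle voting: each edge point votes along +/- its unit
// gradient direction at every candidate radius in [rmin, rmax]. Votes are
// binned per radius; the best (center, radius) cell after 3x3 spatial
// smoothing is returned as (cx, cy, r, votes).
// [[Rcpp::export]]
NumericVector cpp_hough_circle(const NumericVector& ex, const NumericVector& ey,
                               const NumericVector& ux, const NumericVector& uy,
                               int H, int W, double rmin, double rmax) {
  const int ne = ex.size();
  std::vector<double> acc((size_t)H * W);
  double best = -1.0, bx = 0, by = 0, br = 0;
  for (double r = rmin; r <= rmax; r += 1.0) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < ne; ++i) {
      for (int s = -1; s <= 1; s += 2) {
        const int cx = (int)std::lround(ex[i] + s * r * ux[i]);
        const int cy = (int)std::lround(ey[i] + s * r * uy[i]);
        if (cx >= 0 && cx < W && cy >= 0 && cy < H) acc[(size_t)cy * W + cx] += 1.0;
      }
    }
    for (int y = 1; y < H - 1; ++y) {
      for (int x = 1; x < W - 1; ++x) {
        double s9 = 0.0;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx)
            s9 += acc[(size_t)(y + dy) * W + (x + dx)];
        if (s9 > best) { best = s9; bx = x; by = y; br = r; }
      }
    }
  }
  return NumericVector::create(bx, by, br, best);
}
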