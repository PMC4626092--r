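// Pixel-loop primitives for the 8-bit filter stack and binary morphology.
// All filters use replicate (clamp-to-edge) padding; the circular
// neighbourhood of radius r is the set of offsets with dx^2 + dy^2 <= r^2.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Offsets of the Euclidean disk of radius r (r >= 1, integer offsets).
static void disk_offsets(double radius, std::vector<int>& dr,
                         std::vector<int>& dc) {
  int r = (int)std::floor(radius);
  double r2 = radius * radius;
  for (int i = -r; i <= r; ++i)
    for (int j = -r; j <= r; ++j)
      if ((double)(i * i + j * j) <= r2) {
        dr.push_back(i);
        dc.push_back(j);
      }
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& w : k) w /= s;
  // full 2D convolution with the separable (outer-product) kernel,
  // accumulated per-pixel so results match a naive reference bit-for-bit
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int di = -rad; di <= rad; ++di) {
        int ii = clampi(i + di, 0, nr - 1);
        double wrow = k[di + rad];
        for (int dj = -rad; dj <= rad; ++dj) {
          int jj = clampi(j + dj, 0, nc - 1);
          acc += wrow * k[dj + rad] * img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  return out;
}

// Separable variant (row then column pass): same kernel as
// cpp_gaussian_blur up to floating-point association; used where speed
// matters (blob detection at large sigma), not in the oracle-checked stack.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur_sep(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& w : k) w /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * img(clampi(i + d, 0, nr - 1), j);
      tmp(i, j) = acc;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * tmp(i, clampi(j + d, 0, nc - 1));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sobel_magnitude(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  // gx responds to horizontal gradients (column direction), gy to vertical
  const int kx[3][3] = {{-1, 0, 1}, {-2, 0, 2}, {-1, 0, 1}};
  const int ky[3][3] = {{-1, -2, -1}, {0, 0, 0}, {1, 2, 1}};
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double gx = 0.0, gy = 0.0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          double v = img(clampi(i + di, 0, nr - 1), clampi(j + dj, 0, nc - 1));
          gx += kx[di + 1][dj + 1] * v;
          gy += ky[di + 1][dj + 1] * v;
        }
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_local_variance(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  disk_offsets(radius, dr, dc);
  int n = (int)dr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(n);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = 0.0;
      for (int t = 0; t < n; ++t) {
        buf[t] = img(clampi(i + dr[t], 0, nr - 1), clampi(j + dc[t], 0, nc - 1));
        m += buf[t];
      }
      m /= n;
      double ss = 0.0;
      for (int t = 0; t < n; ++t) ss += (buf[t] - m) * (buf[t] - m);
      out(i, j) = ss / n;  // population variance
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_local_median(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  disk_offsets(radius, dr, dc);
  int n = (int)dr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(n);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      for (int t = 0; t < n; ++t)
        buf[t] = img(clampi(i + dr[t], 0, nr - 1), clampi(j + dc[t], 0, nc - 1));
      std::sort(buf.begin(), buf.end());
      out(i, j) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  return out;
}

// 8-connected component labelling; labels contiguous from 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(LogicalMatrix mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (radius <= 0) return clone(mask);
  std::vector<int> dr, dc;
  disk_offsets(radius, dr, dc);
  int n = (int)dr.size();
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      for (int t = 0; t < n; ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
      }
    }
  return out;
}

// Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  // neighbours P2..P9 clockwise starting from north
  const int di[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) {
          if (!img(i, j)) continue;
          int p[8], b = 0, a = 0;
          for (int t = 0; t < 8; ++t) {
            int ii = i + di[t], jj = j + dj[t];
            p[t] = (ii >= 0 && ii < nr && jj >= 0 && jj < nc && img(ii, jj))
                       ? 1 : 0;
            b += p[t];
          }
          for (int t = 0; t < 8; ++t)
            if (p[t] == 0 && p[(t + 1) % 8] == 1) ++a;
          if (b < 2 || b > 6 || a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          kill.push_back(std::make_pair(i, j));
        }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t)
        img(kill[t].first, kill[t].second) = false;
    }
  }
  return img;
}

// Render a tube: union of Euclidean disks of the given radius centred on
// each (row, col) path vertex (0-based continuous coordinates).
// [[Rcpp::export]]
LogicalMatrix cpp_draw_tube(int nrow, int ncol, NumericVector pr,
                            NumericVector pc, double radius) {
  LogicalMatrix out(nrow, ncol);
  int n = pr.size();
  int r = (int)std::ceil(radius);
  double r2 = radius * radius;
  for (int t = 0; t < n; ++t) {
    int ci = (int)std::lround(pr[t]), cj = (int)std::lround(pc[t]);
    for (int i = std::max(0, ci - r); i <= std::min(nrow - 1, ci + r); ++i)
      for (int j = std::max(0, cj - r); j <= std::min(ncol - 1, cj + r); ++j) {
        double dy = i - pr[t], dx = j - pc[t];
        if (dy * dy + dx * dx <= r2) out(i, j) = true;
      }
  }
  return out;
}

// Add isotropic 2D Gaussian bumps (amplitude * exp(-d^2 / (2 s^2))) at the
// given centres, truncated at 3 s; accumulates into img in place semantics
// (returns a modified copy).
// [[Rcpp::export]]
NumericMatrix cpp_add_blobs(NumericMatrix img, NumericVector pr,
                            NumericVector pc, NumericVector amp,
                            NumericVector sd) {
  NumericMatrix out = clone(img);
  int nr = out.nrow(), nc = out.ncol(), n = pr.size();
  for (int t = 0; t < n; ++t) {
    double s = sd[t];
    int r = (int)std::ceil(3.0 * s);
    int ci = (int)std::lround(pr[t]), cj = (int)std::lround(pc[t]);
    for (int i = std::max(0, ci - r); i <= std::min(nr - 1, ci + r); ++i)
      for (int j = std::max(0, cj - r); j <= std::min(nc - 1, cj + r); ++j) {
        double dy = i - pr[t], dx = j - pc[t];
        out(i, j) += amp[t] * std::exp(-0.5 * (dy * dy + dx * dx) / (s * s));
      }
  }
  return out;
}

// 3x3-neighbourhood local maxima (strictly greater than or equal, with
// strict inequality against at least being the max) above a threshold.
// Returns a 3-column matrix (row, col, value), 1-based indices.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericMatrix img, double threshold) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> rr, cc, vv;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double v = img(i, j);
      if (v <= threshold) continue;
      bool ismax = true;
      for (int di = -1; di <= 1 && ismax; ++di)
        for (int dj = -1; dj <= 1 && ismax; ++dj) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (img(ii, jj) > v) ismax = false;
        }
      if (ismax) {
        rr.push_back(i + 1);
        cc.push_back(j + 1);
        vv.push_back(v);
      }
    }
  NumericMatrix out((int)rr.size(), 3);
  for (size_t t = 0; t < rr.size(); ++t) {
    out(t, 0) = rr[t];
    out(t, 1) = cc[t];
    out(t, 2) = vv[t];
  }
  return out;
}
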