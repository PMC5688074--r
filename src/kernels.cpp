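#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Linear index helpers for column-major 3D arrays.
static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable convolution along one axis with replicate-edge padding.
// axis: 0 = x, 1 = y, 2 = z. Kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int r = kl / 2;
  NumericVector out(arr.size());
  const int nax[3] = {nx, ny, nz};
  const int n = nax[axis];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int xx = x, yy = y, zz = z;
          if (axis == 0) xx = clampi(x + k, 0, n - 1);
          else if (axis == 1) yy = clampi(y + k, 0, n - 1);
          else zz = clampi(z + k, 0, n - 1);
          acc += kernel[k + r] * arr[lin(xx, yy, zz, nx, ny)];
        }
        out[lin(x, y, z, nx, ny)] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Per-voxel parameters (mean, population std, mode, entropy) of the intensity
// histogram within a cubic neighborhood, replicate-edge padded. The histogram
// spans the neighborhood's own [min, max] range with n_bins bins; a flat
// neighborhood occupies a single bin. Entropy = -sum p_i log2(p_i + eps) over
// occupied bins; mode is the center of the most populated bin (lowest-index
// bin on ties), or the constant value for a flat neighborhood.
// [[Rcpp::export]]
List local_hist_cpp(NumericVector arr, IntegerVector dims, int edge,
                    int n_bins, double eps) {
  if (edge % 2 == 0) stop("neighborhood edge must be odd");
  if (n_bins < 2) stop("n_bins must be >= 2");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (edge > nx || edge > ny || edge > nz)
    stop("neighborhood larger than grid");
  const int r = edge / 2;
  const int nn = edge * edge * edge;
  NumericVector mmean(arr.size()), msd(arr.size()), mmode(arr.size()),
      ment(arr.size());
  std::vector<double> buf(nn);
  std::vector<int> counts(n_bins);
  const double log2e = 1.0 / std::log(2.0);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double sum = 0.0, sumsq = 0.0;
        double vmin = std::numeric_limits<double>::infinity();
        double vmax = -vmin;
        int m = 0;
        for (int dz = -r; dz <= r; ++dz) {
          int zz = clampi(z + dz, 0, nz - 1);
          for (int dy = -r; dy <= r; ++dy) {
            int yy = clampi(y + dy, 0, ny - 1);
            for (int dx = -r; dx <= r; ++dx) {
              int xx = clampi(x + dx, 0, nx - 1);
              double v = arr[lin(xx, yy, zz, nx, ny)];
              buf[m++] = v;
              sum += v;
              sumsq += v * v;
              if (v < vmin) vmin = v;
              if (v > vmax) vmax = v;
            }
          }
        }
        const int idx = lin(x, y, z, nx, ny);
        double mean = sum / nn;
        double var = sumsq / nn - mean * mean;
        if (var < 0) var = 0;
        mmean[idx] = mean;
        msd[idx] = std::sqrt(var);
        if (vmax == vmin) {
          mmode[idx] = vmin;
          ment[idx] = -std::log(1.0 + eps) * log2e;
        } else {
          std::fill(counts.begin(), counts.end(), 0);
          const double bw = (vmax - vmin) / n_bins;
          for (int i = 0; i < nn; ++i) {
            int b = (int)((buf[i] - vmin) / bw);
            if (b >= n_bins) b = n_bins - 1;
            counts[b]++;
          }
          int best = 0;
          double ent = 0.0;
          for (int b = 0; b < n_bins; ++b) {
            if (counts[b] > counts[best]) best = b;
            if (counts[b] > 0) {
              double p = (double)counts[b] / nn;
              ent -= p * std::log(p + eps) * log2e;
            }
          }
          mmode[idx] = vmin + (best + 0.5) * bw;
          ment[idx] = ent;
        }
      }
    }
  }
  mmean.attr("dim") = dims;
  msd.attr("dim") = dims;
  mmode.attr("dim") = dims;
  ment.attr("dim") = dims;
  return List::create(_["mean"] = mmean, _["sd"] = msd, _["mode"] = mmode,
                      _["entropy"] = ment);
}

// Connected-component labeling of a binary volume (BFS). connectivity must be
// 6 or 26. Labels are 1..k in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < mask.size(); ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            int nb = lin(x, y, z, nx, ny);
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next;
              q.push(nb);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Number of foreground voxels within the (2r+1)^3 box around each voxel,
// excluding the center. Voxels outside the image count as background.
// [[Rcpp::export]]
IntegerVector neighbor_count_cpp(LogicalVector mask, IntegerVector dims,
                                 int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(mask.size(), 0);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int cnt = 0;
        for (int dz = -radius; dz <= radius; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -radius; dy <= radius; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -radius; dx <= radius; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              if (mask[lin(xx, yy, zz, nx, ny)]) cnt++;
            }
          }
        }
        out[lin(x, y, z, nx, ny)] = cnt;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Foreground voxels with at least one background 6-neighbor (out-of-bounds
// counts as background).
// [[Rcpp::export]]
LogicalVector boundary6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size(), false);
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int idx = lin(x, y, z, nx, ny);
        if (!mask[idx]) continue;
        for (int k = 0; k < 6; ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
              !mask[lin(xx, yy, zz, nx, ny)]) {
            out[idx] = true;
            break;
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
// with sample spacing s. f holds squared distances; INF where no seed.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double s) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) {  // no finite parabola yet
      v[0] = q;
      continue;
    }
    double sq = q * s;
    double sv = v[k] * s;
    double sint = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
    while (sint <= zb[k]) {
      k--;
      sv = v[k] * s;
      sint = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
    }
    k++;
    v[k] = q;
    zb[k] = sint;
    zb[k + 1] = INF;
  }
  if (f[v[0]] == INF) {  // whole line empty
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = q * s;
    while (zb[k + 1] < sq) k++;
    double dv = sq - v[k] * s;
    d[q] = dv * dv + f[v[k]];
  }
}

// Exact Euclidean distance (in physical units, given per-axis spacing) from
// every voxel to the nearest TRUE voxel of the seed mask. Seed voxels get 0.
// Returns +Inf everywhere if the seed mask is empty.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector seed, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(seed.size());
  std::vector<double> g(seed.size());
  for (int i = 0; i < seed.size(); ++i) g[i] = seed[i] ? 0.0 : INF;
  // transform along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
      }
  }
  // along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
      }
  }
  // along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
      }
  }
  for (int i = 0; i < out.size(); ++i)
    out[i] = std::isinf(g[i]) ? INF : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Eigenvalues of voxel-wise symmetric 3x3 matrices (trigonometric closed
// form), sorted by ascending absolute value.
// [[Rcpp::export]]
List eig3x3_cpp(NumericVector xx, NumericVector yy, NumericVector zz,
                NumericVector xy, NumericVector xz, NumericVector yz) {
  const int n = xx.size();
  NumericVector l1(n), l2(n), l3(n);
  const double pi = 3.14159265358979323846;
  for (int i = 0; i < n; ++i) {
    double a = xx[i], b = yy[i], c = zz[i], d = xy[i], e = xz[i], f = yz[i];
    double ev[3];
    double p1 = d * d + e * e + f * f;
    if (p1 < 1e-300) {
      ev[0] = a; ev[1] = b; ev[2] = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // det((A - qI)/p) / 2
      double ba = (a - q) / p, bb = (b - q) / p, bc = (c - q) / p;
      double bd = d / p, be = e / p, bf = f / p;
      double detB = ba * (bb * bc - bf * bf) - bd * (bd * bc - bf * be) +
                    be * (bd * bf - bb * be);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      ev[0] = q + 2.0 * p * std::cos(phi);
      ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * pi / 3.0);
      ev[1] = 3.0 * q - ev[0] - ev[2];
    }
    // sort by |lambda| ascending
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(ev[t]) > std::fabs(ev[t + 1])) {
          double tmp = ev[t]; ev[t] = ev[t + 1]; ev[t + 1] = tmp;
        }
    l1[i] = ev[0]; l2[i] = ev[1]; l3[i] = ev[2];
  }
  SEXP dm = xx.attr("dim");
  if (dm != R_NilValue) {
    l1.attr("dim") = dm; l2.attr("dim") = dm; l3.attr("dim") = dm;
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
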