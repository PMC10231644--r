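#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// ---- epsilon-SVR (bias-free dual, coordinate descent) ----------------------
//
// Solves, for each column y of Y,
//   min_b  0.5 * b' K b - y' b + eps * ||b||_1   s.t. |b_i| <= C
// which is the dual of bias-free epsilon-SVR on a precomputed kernel K.
// The response is assumed centered (the pipeline z-scores behavior), so the
// usual equality constraint sum(b) = 0 tied to the intercept is dropped.

static inline double soft_threshold(double g, double eps) {
  if (g > eps) return g - eps;
  if (g < -eps) return g + eps;
  return 0.0;
}

// [[Rcpp::export]]
NumericMatrix esvr_fit_multi(const NumericMatrix& K, const NumericMatrix& Y,
                             double cost, double eps, double tol = 1e-8,
                             int max_sweeps = 2000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (Y.nrow() != n) stop("Y rows must match kernel dimension");
  const int m = Y.ncol();
  NumericMatrix A(n, m);
  std::vector<double> f(n);

  for (int col = 0; col < m; ++col) {
    std::fill(f.begin(), f.end(), 0.0);
    double* a = &A(0, col);
    const double* y = &Y(0, col);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double max_delta = 0.0;
      for (int i = 0; i < n; ++i) {
        const double kii = K(i, i);
        double ai_new;
        if (kii <= 0.0) {
          ai_new = 0.0;
        } else {
          // gradient of smooth part excluding i's own contribution
          const double g = y[i] - (f[i] - kii * a[i]);
          ai_new = soft_threshold(g, eps) / kii;
          if (ai_new > cost) ai_new = cost;
          if (ai_new < -cost) ai_new = -cost;
        }
        const double delta = ai_new - a[i];
        if (delta != 0.0) {
          a[i] = ai_new;
          const double* kcol = &K(0, i);
          for (int j = 0; j < n; ++j) f[j] += delta * kcol[j];
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) break;
    }
  }
  return A;
}

// ---- IIR filtering (direct form II transposed, column-wise) ----------------
// [[Rcpp::export]]
NumericMatrix iir_filter_cpp(const NumericVector& b, const NumericVector& a,
                             const NumericMatrix& X,
                             Nullable<NumericVector> zi = R_NilValue,
                             Nullable<NumericVector> zi_scale = R_NilValue) {
  const int nb = b.size(), na = a.size(), T = X.nrow(), m = X.ncol();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> bn(nz + 1, 0.0), an(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) an[i] = a[i] / a[0];
  NumericMatrix Y(T, m);
  std::vector<double> z(nz);
  NumericVector zi_(nz), sc_(m);
  bool use_zi = zi.isNotNull();
  if (use_zi) {
    zi_ = NumericVector(zi);
    if (zi_.size() != nz) stop("zi must have length max(nb,na)-1");
    sc_ = zi_scale.isNotNull() ? NumericVector(zi_scale)
                               : NumericVector(m, 1.0);
    if (sc_.size() != m) stop("zi_scale must have one value per column");
  }
  for (int c = 0; c < m; ++c) {
    if (use_zi)
      for (int k = 0; k < nz; ++k) z[k] = zi_[k] * sc_[c];
    else
      std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const double x = X(t, c);
      const double y = bn[0] * x + z[0];
      for (int k = 0; k < nz - 1; ++k)
        z[k] = bn[k + 1] * x + z[k + 1] - an[k + 1] * y;
      if (nz > 0) z[nz - 1] = bn[nz] * x - an[nz] * y;
      Y(t, c) = y;
    }
  }
  return Y;
}

// ---- connected components --------------------------------------------------

static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        const int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

static void label_grid(const int* grid, const int* dims, int connectivity,
                       int* labels, std::vector<int>& sizes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int noff = (int)dx.size();
  std::fill(labels, labels + n, 0);
  sizes.clear();
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!grid[s] || labels[s]) continue;
    ++next;
    int sz = 0;
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      ++sz;
      const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((long)nx * ny));
      for (int k = 0; k < noff; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        const long w = xx + (long)nx * (yy + (long)ny * zz);
        if (grid[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(sz);
  }
}

// [[Rcpp::export]]
List label_components_3d(const IntegerVector& grid, const IntegerVector& dims,
                         int connectivity = 26) {
  if (dims.size() != 3) stop("dims must have length 3");
  const long n = (long)dims[0] * dims[1] * dims[2];
  if (grid.size() != n) stop("grid length does not match dims");
  IntegerVector labels(n);
  std::vector<int> sizes;
  label_grid(grid.begin(), dims.begin(), connectivity, labels.begin(), sizes);
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Max cluster size per column of a thresholded in-mask statistic matrix.
// thr: nvox_in_mask x ncol logical; vox_idx: 0-based linear grid indices.
// [[Rcpp::export]]
IntegerVector perm_max_cluster(const LogicalMatrix& thr,
                               const IntegerVector& vox_idx,
                               const IntegerVector& dims,
                               int connectivity = 26) {
  const int nv = thr.nrow(), m = thr.ncol();
  if (vox_idx.size() != nv) stop("vox_idx length mismatch");
  const long n = (long)dims[0] * dims[1] * dims[2];
  std::vector<int> grid(n, 0), labels(n, 0);
  std::vector<int> sizes;
  IntegerVector out(m);
  for (int c = 0; c < m; ++c) {
    for (int i = 0; i < nv; ++i) grid[vox_idx[i]] = thr(i, c) ? 1 : 0;
    label_grid(grid.data(), dims.begin(), connectivity, labels.data(), sizes);
    int mx = 0;
    for (size_t k = 0; k < sizes.size(); ++k) if (sizes[k] > mx) mx = sizes[k];
    out[c] = mx;
    for (int i = 0; i < nv; ++i) grid[vox_idx[i]] = 0;
  }
  return out;
}

// ---- permutation tail probabilities ----------------------------------------
// For each row, p_ik = #{j : B_ij >= B_ik} / ncol  (upper-tail rank including
// self, so min p = 1/ncol when the observed value sits in column 1).
// [[Rcpp::export]]
NumericMatrix tail_p_rows(const NumericMatrix& B) {
  const int nr = B.nrow(), nc = B.ncol();
  NumericMatrix P(nr, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = B(i, j);
    std::sort(row.begin(), row.end());
    for (int j = 0; j < nc; ++j) {
      const double v = B(i, j);
      const int pos = (int)(std::lower_bound(row.begin(), row.end(), v) - row.begin());
      P(i, j) = (double)(nc - pos) / (double)nc;
    }
  }
  return P;
}

// ---- streamline voxel traversal (Amanatides & Woo) -------------------------
// Points are in continuous 0-based voxel coordinates; voxel i spans
// [i - 0.5, i + 0.5). Visits every voxel a segment passes through.

static inline long vox_linear(int x, int y, int z, const int* dims) {
  if (x < 0 || y < 0 || z < 0 || x >= dims[0] || y >= dims[1] || z >= dims[2])
    return -1;
  return x + (long)dims[0] * (y + (long)dims[1] * z);
}

static void traverse_segment(const double* p, const double* q, const int* dims,
                             std::vector<long>& visited) {
  int iv[3], ev[3], step[3];
  double tMax[3], tDelta[3], d[3];
  for (int a = 0; a < 3; ++a) {
    iv[a] = (int)std::floor(p[a] + 0.5);
    ev[a] = (int)std::floor(q[a] + 0.5);
    d[a] = q[a] - p[a];
    if (d[a] > 0) {
      step[a] = 1;
      tMax[a] = ((iv[a] + 0.5) - p[a]) / d[a];
      tDelta[a] = 1.0 / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      tMax[a] = ((iv[a] - 0.5) - p[a]) / d[a];
      tDelta[a] = -1.0 / d[a];
    } else {
      step[a] = 0;
      tMax[a] = R_PosInf;
      tDelta[a] = R_PosInf;
    }
  }
  long lin = vox_linear(iv[0], iv[1], iv[2], dims);
  if (lin >= 0) visited.push_back(lin);
  const int guard = std::abs(ev[0] - iv[0]) + std::abs(ev[1] - iv[1]) +
                    std::abs(ev[2] - iv[2]) + 3;
  for (int it = 0; it < guard; ++it) {
    if (iv[0] == ev[0] && iv[1] == ev[1] && iv[2] == ev[2]) break;
    int m = 0;
    if (tMax[1] < tMax[m]) m = 1;
    if (tMax[2] < tMax[m]) m = 2;
    if (tMax[m] > 1.0 + 1e-12) break;
    iv[m] += step[m];
    tMax[m] += tDelta[m];
    lin = vox_linear(iv[0], iv[1], iv[2], dims);
    if (lin >= 0) visited.push_back(lin);
  }
}

// Voxels visited by one polyline (rows = ordered points, voxel coords).
// [[Rcpp::export]]
IntegerVector streamline_voxels(const NumericMatrix& pts, const IntegerVector& dims) {
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  std::vector<long> visited;
  double p[3], q[3];
  for (int i = 0; i + 1 < pts.nrow(); ++i) {
    for (int a = 0; a < 3; ++a) { p[a] = pts(i, a); q[a] = pts(i + 1, a); }
    traverse_segment(p, q, dims.begin(), visited);
  }
  std::sort(visited.begin(), visited.end());
  visited.erase(std::unique(visited.begin(), visited.end()), visited.end());
  IntegerVector out(visited.size());
  for (size_t i = 0; i < visited.size(); ++i) out[i] = (int)visited[i];
  return out;  // 0-based linear indices
}

// Union of voxels visited by streamlines intersecting a lesion.
// pts: all points stacked; offsets: 0-based start index of each streamline,
// plus a terminal offset equal to nrow(pts). mode: 0 = segment traversal,
// 1 = vertex membership only (for the lesion test AND the visitation map).
// [[Rcpp::export]]
LogicalVector disconnection_map_cpp(const NumericMatrix& pts,
                                    const IntegerVector& offsets,
                                    const LogicalVector& lesion,
                                    const IntegerVector& dims,
                                    int mode = 0) {
  const long n = (long)dims[0] * dims[1] * dims[2];
  if (lesion.size() != n) stop("lesion length does not match dims");
  LogicalVector out(n);
  const int ns = offsets.size() - 1;
  std::vector<long> visited;
  double p[3], q[3];
  for (int s = 0; s < ns; ++s) {
    visited.clear();
    const int from = offsets[s], to = offsets[s + 1];
    if (mode == 0) {
      for (int i = from; i + 1 < to; ++i) {
        for (int a = 0; a < 3; ++a) { p[a] = pts(i, a); q[a] = pts(i + 1, a); }
        traverse_segment(p, q, dims.begin(), visited);
      }
    } else {
      for (int i = from; i < to; ++i) {
        const long lin = vox_linear((int)std::floor(pts(i, 0) + 0.5),
                                    (int)std::floor(pts(i, 1) + 0.5),
                                    (int)std::floor(pts(i, 2) + 0.5), dims.begin());
        if (lin >= 0) visited.push_back(lin);
      }
    }
    bool hit = false;
    for (size_t k = 0; k < visited.size(); ++k)
      if (lesion[visited[k]]) { hit = true; break; }
    if (hit)
      for (size_t k = 0; k < visited.size(); ++k) out[visited[k]] = true;
  }
  return out;
}
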