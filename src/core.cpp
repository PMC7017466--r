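// Low-level voxel and tomography primitives.
//
// Conventions shared with the R level:
//  - 3D arrays are R arrays in column-major order, dims = c(nx, ny, nz);
//    the R level maps (x, y, z) world axes onto dims 1..3 with z vertical.
//  - masks are logical arrays; labels are integer arrays with 0 = background.
//  - all distances are in the units of the `spacing` arguments (mm).

#include <Rcpp.h>
#include <map>
#include <array>
#include <list>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static void neighbour_offsets(int connectivity, int nx, int ny,
                              std::vector<std::array<int, 3>>& out) {
  out.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        out.push_back({dx, dy, dz});
      }
  (void)nx; (void)ny;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;

  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, nx, ny, off);

  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back((int)start);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int nb = idx3(xx, yy, zz, nx, ny);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, anisotropic spacing. Distance of each TRUE voxel to the nearest
// FALSE voxel; the volume border is treated as interior (the R wrapper pads
// with a background layer when outside-the-volume must count as background).

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -1e300;  // sentinels must dominate any parabola intersection
  zb[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q * h * h) - (f[p] + (double)p * p * h * h)) /
          (2.0 * h * h * (q - p));
      if (s <= zb[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  if (spacing.size() != 3) stop("spacing must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  NumericVector out(n);
  const double INF = 1e100;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[idx3(x, y, z, nx, ny)] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[idx3(x, y, z, nx, ny)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[idx3(x, y, z, nx, ny)] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[idx3(x, y, z, nx, ny)] = d[z];
    }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable box maximum filter with integer half-widths per axis.

static void maxfilt_axis(std::vector<double>& buf, std::vector<double>& tmp,
                         int n, int w) {
  if (w <= 0) return;
  for (int i = 0; i < n; ++i) {
    double m = buf[i];
    int lo = std::max(0, i - w), hi = std::min(n - 1, i + w);
    for (int j = lo; j <= hi; ++j)
      if (buf[j] > m) m = buf[j];
    tmp[i] = m;
  }
  std::copy(tmp.begin(), tmp.end(), buf.begin());
}

// [[Rcpp::export]]
NumericVector cpp_box_max_filter(NumericVector x, IntegerVector halfwidth) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 3) stop("x must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(x);
  std::vector<double> buf, tmp;
  buf.resize(nx); tmp.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x0 = 0; x0 < nx; ++x0) buf[x0] = out[idx3(x0, y, z, nx, ny)];
      maxfilt_axis(buf, tmp, nx, halfwidth[0]);
      for (int x0 = 0; x0 < nx; ++x0) out[idx3(x0, y, z, nx, ny)] = buf[x0];
    }
  buf.resize(ny); tmp.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x0 = 0; x0 < nx; ++x0) {
      for (int y = 0; y < ny; ++y) buf[y] = out[idx3(x0, y, z, nx, ny)];
      maxfilt_axis(buf, tmp, ny, halfwidth[1]);
      for (int y = 0; y < ny; ++y) out[idx3(x0, y, z, nx, ny)] = buf[y];
    }
  buf.resize(nz); tmp.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x0 = 0; x0 < nx; ++x0) {
      for (int z = 0; z < nz; ++z) buf[z] = out[idx3(x0, y, z, nx, ny)];
      maxfilt_axis(buf, tmp, nz, halfwidth[2]);
      for (int z = 0; z < nz; ++z) out[idx3(x0, y, z, nx, ny)] = buf[z];
    }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flooding: voxels are popped in order of
// increasing elevation (use -distance for basin splitting); each unassigned
// mask voxel inherits the label of the flood that reaches it first.

struct PQItem {
  double elev;
  long order;
  int idx;
  int label;
};
struct PQCmp {
  bool operator()(const PQItem& a, const PQItem& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order;  // FIFO tie-break for determinism
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector elevation, IntegerVector markers,
                            LogicalVector mask) {
  IntegerVector dims = elevation.attr("dim");
  if (dims.size() != 3) stop("elevation must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = elevation.size();
  if (markers.size() != n || mask.size() != n)
    stop("markers/mask must match elevation in size");

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i])
      pq.push({elevation[i], order++, (int)i, markers[i]});

  std::vector<std::array<int, 3>> off;
  neighbour_offsets(26, nx, ny, off);

  while (!pq.empty()) {
    PQItem it = pq.top();
    pq.pop();
    if (labels[it.idx] != 0) continue;
    labels[it.idx] = it.label;
    int z = it.idx / (nx * ny);
    int rem = it.idx - z * nx * ny;
    int y = rem / nx;
    int x = rem - y * nx;
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int nb = idx3(xx, yy, zz, nx, ny);
      if (mask[nb] && labels[nb] == 0)
        pq.push({elevation[nb], order++, nb, it.label});
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Exact smallest enclosing sphere in 3D, Welzl's algorithm in Gaertner's
// move-to-front form (recursion depth bounded by the support size, <= 5).

typedef std::array<double, 3> P3;

struct Ball {
  P3 c;
  double r2;  // squared radius; -1 = empty
};

static double dist2(const P3& a, const P3& b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// smallest sphere with all support points on its boundary (0..4 points)
static Ball ball_from_support(const std::vector<P3>& s) {
  Ball b;
  b.c = {0, 0, 0};
  b.r2 = -1.0;
  const size_t m = s.size();
  if (m == 0) return b;
  if (m == 1) {
    b.c = s[0];
    b.r2 = 0.0;
    return b;
  }
  if (m == 2) {
    for (int k = 0; k < 3; ++k) b.c[k] = 0.5 * (s[0][k] + s[1][k]);
    b.r2 = dist2(b.c, s[0]);
    return b;
  }
  // 3 or 4 points: solve for centre as s[0] + sum lambda_i * (s[i]-s[0])
  // from (c - s0).(si - s0) = |si - s0|^2 / 2.
  double A[3][3] = {{0}};
  double rhs[3] = {0};
  int dim = (int)m - 1;
  double v[3][3];
  for (int i = 0; i < dim; ++i)
    for (int k = 0; k < 3; ++k) v[i][k] = s[i + 1][k] - s[0][k];
  for (int i = 0; i < dim; ++i) {
    for (int j = 0; j < dim; ++j)
      A[i][j] = 2.0 * (v[i][0] * v[j][0] + v[i][1] * v[j][1] + v[i][2] * v[j][2]);
    rhs[i] = v[i][0] * v[i][0] + v[i][1] * v[i][1] + v[i][2] * v[i][2];
  }
  // Gaussian elimination with partial pivoting on dim x dim system
  int piv[3] = {0, 1, 2};
  for (int col = 0; col < dim; ++col) {
    int best = col;
    for (int r = col + 1; r < dim; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[best][col])) best = r;
    if (std::fabs(A[best][col]) < 1e-14) return b;  // degenerate -> empty
    if (best != col) {
      for (int k = 0; k < dim; ++k) std::swap(A[col][k], A[best][k]);
      std::swap(rhs[col], rhs[best]);
      std::swap(piv[col], piv[best]);
    }
    for (int r = col + 1; r < dim; ++r) {
      double f = A[r][col] / A[col][col];
      for (int k = col; k < dim; ++k) A[r][k] -= f * A[col][k];
      rhs[r] -= f * rhs[col];
    }
  }
  double lam[3] = {0, 0, 0};
  for (int r = dim - 1; r >= 0; --r) {
    double acc = rhs[r];
    for (int k = r + 1; k < dim; ++k) acc -= A[r][k] * lam[k];
    lam[r] = acc / A[r][r];
  }
  b.c = s[0];
  for (int i = 0; i < dim; ++i)
    for (int k = 0; k < 3; ++k) b.c[k] += lam[i] * v[i][k];
  b.r2 = dist2(b.c, s[0]);
  return b;
}

static bool in_ball(const Ball& b, const P3& p, double eps) {
  if (b.r2 < 0) return false;
  return dist2(b.c, p) <= b.r2 + eps;
}

static Ball mtf_mb(std::list<P3>& L, std::list<P3>::iterator end,
                   std::vector<P3>& support, double eps) {
  Ball mb = ball_from_support(support);
  if (support.size() == 4) return mb;
  for (auto it = L.begin(); it != end;) {
    auto cur = it++;
    if (!in_ball(mb, *cur, eps)) {
      support.push_back(*cur);
      mb = mtf_mb(L, cur, support, eps);
      support.pop_back();
      L.splice(L.begin(), L, cur);  // move-to-front
    }
  }
  return mb;
}

// [[Rcpp::export]]
NumericVector cpp_min_sphere(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 1) stop("need at least one point");
  if (pts.ncol() != 3) stop("pts must be n x 3");
  std::vector<P3> v(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    v[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    for (int k = 0; k < 3; ++k) scale = std::max(scale, std::fabs(v[i][k]));
  }
  double eps = 1e-12 * std::max(1.0, scale * scale);
  // deterministic shuffle (independent of R's RNG state)
  std::mt19937 rng(88172645u);
  std::shuffle(v.begin(), v.end(), rng);
  std::list<P3> L(v.begin(), v.end());
  std::vector<P3> support;
  Ball b = mtf_mb(L, L.end(), support, eps);
  return NumericVector::create(b.c[0], b.c[1], b.c[2],
                               std::sqrt(std::max(0.0, b.r2)));
}

// ---------------------------------------------------------------------------
// Parallel-beam tomography on one 2D slice. The slice is img(nx, ny) with
// square pixels of size `pix` (mm), centred on the rotation axis. A detector
// bin k sits at signed position s = (k - (ndet-1)/2) * ds along the direction
// (cos a, sin a); the ray runs along (-sin a, cos a).

static inline double bilinear(const NumericMatrix& img, double x, double y) {
  // x, y in pixel index units (0-based); 0 outside
  const int nx = img.nrow(), ny = img.ncol();
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 < -1 || y0 < -1 || x0 > nx - 1 || y0 > ny - 1) return 0.0;
  double fx = x - x0, fy = y - y0;
  double v00 = (x0 >= 0 && y0 >= 0) ? img(x0, y0) : 0.0;
  double v10 = (x0 + 1 < nx && y0 >= 0) ? img(x0 + 1, y0) : 0.0;
  double v01 = (x0 >= 0 && y0 + 1 < ny) ? img(x0, y0 + 1) : 0.0;
  double v11 = (x0 + 1 < nx && y0 + 1 < ny) ? img(x0 + 1, y0 + 1) : 0.0;
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// [[Rcpp::export]]
NumericMatrix cpp_project_slice(NumericMatrix img, NumericVector angles_rad,
                                int ndet, double ds, double pix, double step) {
  const int nx = img.nrow(), ny = img.ncol();
  const int na = angles_rad.size();
  NumericMatrix out(ndet, na);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double half_diag = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) * pix;
  const int nstep = (int)std::ceil(2.0 * half_diag / step);
  for (int a = 0; a < na; ++a) {
    double ca = std::cos(angles_rad[a]), sa = std::sin(angles_rad[a]);
    for (int k = 0; k < ndet; ++k) {
      double s = (k - 0.5 * (ndet - 1)) * ds;
      double acc = 0.0;
      for (int m = 0; m <= nstep; ++m) {
        double t = -half_diag + m * step;
        double x = (s * ca - t * sa) / pix + cx;
        double y = (s * sa + t * ca) / pix + cy;
        acc += bilinear(img, x, y);
      }
      out(k, a) = acc * step;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject_slice(NumericMatrix filt, NumericVector angles_rad,
                                    int nx, int ny, double pix, double ds) {
  const int ndet = filt.nrow();
  const int na = angles_rad.size();
  NumericMatrix out(nx, ny);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int a = 0; a < na; ++a) {
    double ca = std::cos(angles_rad[a]), sa = std::sin(angles_rad[a]);
    for (int j = 0; j < ny; ++j) {
      double y = (j - cy) * pix;
      for (int i = 0; i < nx; ++i) {
        double x = (i - cx) * pix;
        double t = x * ca + y * sa;
        double u = t / ds + 0.5 * (ndet - 1);
        int u0 = (int)std::floor(u);
        if (u0 < -1 || u0 > ndet - 1) continue;
        double fu = u - u0;
        double v0 = (u0 >= 0) ? filt(u0, a) : 0.0;
        double v1 = (u0 + 1 < ndet) ? filt(u0 + 1, a) : 0.0;
        out(i, j) += v0 * (1 - fu) + v1 * fu;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Count mask voxels with at least one face neighbour (6-connectivity) outside
// the mask; voxels beyond the array border count as background.

// [[Rcpp::export]]
int cpp_surface_count(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int count = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[idx3(x, y, z, nx, ny)]) continue;
        bool surf = false;
        if (x == 0 || !mask[idx3(x - 1, y, z, nx, ny)]) surf = true;
        else if (x == nx - 1 || !mask[idx3(x + 1, y, z, nx, ny)]) surf = true;
        else if (y == 0 || !mask[idx3(x, y - 1, z, nx, ny)]) surf = true;
        else if (y == ny - 1 || !mask[idx3(x, y + 1, z, nx, ny)]) surf = true;
        else if (z == 0 || !mask[idx3(x, y, z - 1, nx, ny)]) surf = true;
        else if (z == nz - 1 || !mask[idx3(x, y, z + 1, nx, ny)]) surf = true;
        if (surf) ++count;
      }
  return count;
}

// ---------------------------------------------------------------------------
// Saddle heights between watershed basins: for every pair of adjacent basin
// labels, the maximum over adjacent voxel pairs of min(height_a, height_b).
// Returns a numeric matrix with columns (label_a, label_b, saddle).

// [[Rcpp::export]]
NumericMatrix cpp_basin_saddles(IntegerVector labels, NumericVector height) {
  IntegerVector dims = labels.attr("dim");
  if (dims.size() != 3) stop("labels must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::map<std::pair<int, int>, double> saddle;
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(26, nx, ny, off);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = labels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double ha = height[idx3(x, y, z, nx, ny)];
        for (size_t k = 0; k < off.size(); ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int b = labels[idx3(xx, yy, zz, nx, ny)];
          if (b == 0 || b == a) continue;
          double h = std::min(ha, height[idx3(xx, yy, zz, nx, ny)]);
          std::pair<int, int> key(std::min(a, b), std::max(a, b));
          auto it = saddle.find(key);
          if (it == saddle.end() || h > it->second) saddle[key] = h;
        }
      }
  NumericMatrix out(saddle.size(), 3);
  int r = 0;
  for (auto& kv : saddle) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Column-wise min and max of a matrix (row 1 = min, row 2 = max).

// [[Rcpp::export]]
NumericMatrix cpp_col_range(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericMatrix out(2, k);
  for (int j = 0; j < k; ++j) {
    double lo = x(0, j), hi = x(0, j);
    for (int i = 1; i < n; ++i) {
      double v = x(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    out(0, j) = lo;
    out(1, j) = hi;
  }
  return out;
}
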