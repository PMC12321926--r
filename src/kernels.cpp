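#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grid convention throughout: R column-major arrays with
// dim1 = axial slice (superior -> inferior), dim2 = anterior -> posterior,
// dim3 = right -> left. Linear index = i1 + d1*(i2 + d2*i3).

static inline int lin(int i1, int i2, int i3, int d1, int d2) {
  return i1 + d1 * (i2 + d2 * i3);
}

static void neighbour_offsets(int connectivity,
                              std::vector<int>& o1,
                              std::vector<int>& o2,
                              std::vector<int>& o3) {
  o1.clear(); o2.clear(); o3.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int ord = std::abs(a) + std::abs(b) + std::abs(c);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        o1.push_back(a); o2.push_back(b); o3.push_back(c);
      }
}

// 3-D connected-component labelling by breadth-first flood fill.
// Returns integer labels, 0 = background; labels are in order of discovery.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<int> o1, o2, o3;
  neighbour_offsets(connectivity, o1, o2, o3);
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int i3 = cur / (d1 * d2);
      int rem = cur - i3 * d1 * d2;
      int i2 = rem / d1;
      int i1 = rem - i2 * d1;
      for (size_t k = 0; k < o1.size(); ++k) {
        int j1 = i1 + o1[k], j2 = i2 + o2[k], j3 = i3 + o3[k];
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3) continue;
        int q = lin(j1, j2, j3, d1, d2);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Mean HU over the 3x3 neighbourhood of each voxel, counting only
// neighbours at or above `air_thr` (air voxels are excluded from the mean,
// and the centre voxel never counts). mode 0 = in-plane (axial) 3x3,
// mode 1 = 3x3x3 block. Voxels with no qualifying neighbour get NA.
// [[Rcpp::export(name = ".local_band_mean")]]
NumericVector local_band_mean(NumericVector vol, IntegerVector dim,
                              double air_thr, int mode) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n, NA_REAL);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        double acc = 0.0; int cnt = 0;
        int a_lo = (mode == 1) ? -1 : 0, a_hi = (mode == 1) ? 1 : 0;
        for (int a = a_lo; a <= a_hi; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int j1 = i1 + a, j2 = i2 + b, j3 = i3 + c;
              if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3) continue;
              double v = vol[lin(j1, j2, j3, d1, d2)];
              if (v >= air_thr) { acc += v; ++cnt; }
            }
        if (cnt > 0) out[lin(i1, i2, i3, d1, d2)] = acc / cnt;
      }
  return out;
}

// Adaptive expansion of an initial air mask to its fixed point.
// A candidate voxel is absorbed when (a) air_thr <= HU < soft_thr,
// (b) HU is strictly below its precomputed local band mean, and
// (c) it is connected (through the growing mask) to the initial mask.
// The eligibility test is static, so breadth-first growth reaches the
// order-independent fixed point. Returns the added voxels only.
// [[Rcpp::export(name = ".adaptive_expand_core")]]
LogicalVector adaptive_expand_core(NumericVector vol, LogicalVector initial,
                                   LogicalVector allowed, NumericVector local_mean,
                                   IntegerVector dim, double air_thr, double soft_thr,
                                   int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<int> o1, o2, o3;
  neighbour_offsets(connectivity, o1, o2, o3);
  std::vector<char> in(n, 0);
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s)
    if (initial[s]) { in[s] = 1; stack.push_back((int)s); }
  LogicalVector added(n, false);
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int i3 = cur / (d1 * d2);
    int rem = cur - i3 * d1 * d2;
    int i2 = rem / d1;
    int i1 = rem - i2 * d1;
    for (size_t k = 0; k < o1.size(); ++k) {
      int j1 = i1 + o1[k], j2 = i2 + o2[k], j3 = i3 + o3[k];
      if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3) continue;
      int q = lin(j1, j2, j3, d1, d2);
      if (in[q] || !allowed[q]) continue;
      double v = vol[q];
      if (v < air_thr || v >= soft_thr) continue;
      double m = local_mean[q];
      if (!R_finite(m) || !(v < m)) continue;
      in[q] = 1;
      added[q] = true;
      stack.push_back(q);
    }
  }
  return added;
}

// Separable Gaussian smoothing; sigma given in voxels per dimension,
// dimensions with sigma <= 0 are left untouched. Replicate border.
// [[Rcpp::export(name = ".gauss_blur_3d")]]
NumericVector gauss_blur_3d(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector cur = clone(vol);
  const int stride[3] = {1, d[0], d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (i * i) / (s * s));
      tot += k[i + r];
    }
    for (double& w : k) w /= tot;
    NumericVector nxt(n);
    int da = d[ax], sa = stride[ax];
    // iterate over all lines along axis ax
    int ob = (ax == 0) ? 1 : 0;
    int oc = (ax == 2) ? 1 : 2;
    int db = d[ob], dc = d[oc];
    int sb = stride[ob], sc = stride[oc];
    for (int c = 0; c < dc; ++c)
      for (int b = 0; b < db; ++b) {
        R_xlen_t base = (R_xlen_t)b * sb + (R_xlen_t)c * sc;
        for (int a = 0; a < da; ++a) {
          double acc = 0.0;
          for (int i = -r; i <= r; ++i) {
            int j = a + i;
            if (j < 0) j = 0;
            if (j >= da) j = da - 1;
            acc += k[i + r] * cur[base + (R_xlen_t)j * sa];
          }
          nxt[base + (R_xlen_t)a * sa] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}

static inline void edge_point(const double* A, const double* B,
                              double va, double vb, double level, double* P) {
  double t = (level - va) / (vb - va);
  for (int i = 0; i < 3; ++i) P[i] = A[i] + t * (B[i] - A[i]);
}

static inline double tri_area(const double* a, const double* b, const double* c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double x = u[1] * v[2] - u[2] * v[1];
  double y = u[2] * v[0] - u[0] * v[2];
  double z = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(x * x + y * y + z * z);
}

// Iso-surface area by marching tetrahedra: each grid cube (voxel centres as
// vertices, physical coordinates via spacing) is split into six tetrahedra
// sharing the main diagonal, and the `level` iso-surface is triangulated by
// linear interpolation along edges. Returns total area in mm^2.
// [[Rcpp::export(name = ".surface_area_mt")]]
double surface_area_mt(NumericVector field, IntegerVector dim,
                       NumericVector spacing, double level) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  // corner offsets, bit order (i1, i2, i3)
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double total = 0.0;
  for (int i3 = 0; i3 < d3 - 1; ++i3)
    for (int i2 = 0; i2 < d2 - 1; ++i2)
      for (int i1 = 0; i1 < d1 - 1; ++i1) {
        double v[8]; double pos[8][3];
        bool any_lo = false, any_hi = false;
        for (int k = 0; k < 8; ++k) {
          int j1 = i1 + off[k][0], j2 = i2 + off[k][1], j3 = i3 + off[k][2];
          v[k] = field[lin(j1, j2, j3, d1, d2)];
          if (v[k] < level) any_lo = true; else any_hi = true;
          pos[k][0] = j1 * s1; pos[k][1] = j2 * s2; pos[k][2] = j3 * s3;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int inside[4], nin = 0, nout = 0, iin[4], iout[4];
          for (int k = 0; k < 4; ++k) {
            inside[k] = v[T[k]] >= level;
            if (inside[k]) iin[nin++] = T[k]; else iout[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int lone = (nin == 1) ? iin[0] : iout[0];
            int others[3], m = 0;
            for (int k = 0; k < 4; ++k) if (T[k] != lone) others[m++] = T[k];
            double P[3][3];
            for (int k = 0; k < 3; ++k)
              edge_point(pos[lone], pos[others[k]], v[lone], v[others[k]], level, P[k]);
            total += tri_area(P[0], P[1], P[2]);
          } else {
            // two in, two out: quad with vertices on the four mixed edges
            int a = iin[0], b = iin[1], c = iout[0], dd = iout[1];
            double Pac[3], Pad[3], Pbd[3], Pbc[3];
            edge_point(pos[a], pos[c], v[a], v[c], level, Pac);
            edge_point(pos[a], pos[dd], v[a], v[dd], level, Pad);
            edge_point(pos[b], pos[dd], v[b], v[dd], level, Pbd);
            edge_point(pos[b], pos[c], v[b], v[c], level, Pbc);
            total += tri_area(Pac, Pad, Pbd) + tri_area(Pac, Pbd, Pbc);
          }
        }
      }
  return total;
}
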