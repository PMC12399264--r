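#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D connected-component labeling by breadth-first search.
// mask is a logical array in R's column-major layout with dims d = (nx, ny, nz).
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels, 0 for background, components numbered from 1 in
// decreasing-size-agnostic discovery order (use tabulate() in R for sizes).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int current = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    queue.clear();
    queue.push_back(start);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t idx = queue[head++];
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      R_xlen_t rem = idx - (R_xlen_t)z * nx * ny;
      int y = (int)(rem / nx);
      int x = (int)(rem - (R_xlen_t)y * nx);
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = current;
          queue.push_back(nidx);
        }
      }
    }
  }
  return labels;
}

static inline void interp_point(const double *p0, const double *p1,
                                double f0, double f1, double level, double *out) {
  double t = (level - f0) / (f1 - f0);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  for (int i = 0; i < 3; ++i) out[i] = p0[i] + t * (p1[i] - p0[i]);
}

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// accumulate one triangle (q0,q1,q2); `ref` is a point on the inside used to
// orient the normal outward; adds area and signed (divergence-theorem) volume
static void add_triangle(const double *q0, const double *q1, const double *q2,
                         const double *ref, double &area, double &vol) {
  double e1[3], e2[3], nrm[3];
  for (int i = 0; i < 3; ++i) { e1[i] = q1[i] - q0[i]; e2[i] = q2[i] - q0[i]; }
  cross3(e1, e2, nrm);
  double a2 = std::sqrt(nrm[0]*nrm[0] + nrm[1]*nrm[1] + nrm[2]*nrm[2]);
  area += 0.5 * a2;
  // outward orientation: normal must point away from the inside reference
  double cen[3], d[3];
  for (int i = 0; i < 3; ++i) {
    cen[i] = (q0[i] + q1[i] + q2[i]) / 3.0;
    d[i] = cen[i] - ref[i];
  }
  double s = nrm[0]*d[0] + nrm[1]*d[1] + nrm[2]*d[2];
  double c[3];
  if (s >= 0) {
    cross3(e1, e2, c);
    vol += (q0[0]*c[0] + q0[1]*c[1] + q0[2]*c[2]) / 6.0;
  } else {
    // flipped winding: swap q1/q2
    double e1b[3], e2b[3];
    for (int i = 0; i < 3; ++i) { e1b[i] = q2[i] - q0[i]; e2b[i] = q1[i] - q0[i]; }
    cross3(e1b, e2b, c);
    vol += (q0[0]*c[0] + q0[1]*c[1] + q0[2]*c[2]) / 6.0;
  }
}

// Marching-tetrahedra isosurface of a scalar field (column-major, dims nx,ny,nz)
// at `level`.  Each cell is split into 6 tetrahedra around the 0-6 diagonal.
// Returns c(area, enclosed_volume) in voxel units (multiply by spacing^2 and
// spacing^3 for physical units).
// [[Rcpp::export(name = ".march_tet")]]
NumericVector march_tet(NumericVector field, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  if (field.size() != sz * nz) stop("field length does not match dims");

  // cube corner offsets (standard numbering)
  const int cox[8] = {0,1,1,0,0,1,1,0};
  const int coy[8] = {0,0,1,1,0,0,1,1};
  const int coz[8] = {0,0,0,0,1,1,1,1};
  // six tetrahedra sharing the 0-6 diagonal
  const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
  };

  double area = 0.0, vol = 0.0;
  double fc[8], pc[8][3];

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          R_xlen_t idx = (R_xlen_t)(x + cox[c]) * sx + (R_xlen_t)(y + coy[c]) * sy +
                         (R_xlen_t)(z + coz[c]) * sz;
          fc[c] = field[idx];
          pc[c][0] = x + cox[c]; pc[c][1] = y + coy[c]; pc[c][2] = z + coz[c];
          if (fc[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int inside[4], nin = 0, nout = 0, outv[4];
          for (int v = 0; v < 4; ++v) {
            if (fc[tv[v]] >= level) inside[nin++] = v; else outv[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;
          double q[4][3];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? inside[0] : outv[0];
            const int *oth = (nin == 1) ? outv : inside;
            for (int v = 0; v < 3; ++v)
              interp_point(pc[tv[apex]], pc[tv[oth[v]]],
                           fc[tv[apex]], fc[tv[oth[v]]], level, q[v]);
            // reference inside point
            const double *ref = (nin == 1) ? pc[tv[apex]] : pc[tv[inside[0]]];
            add_triangle(q[0], q[1], q[2], ref, area, vol);
          } else { // nin == 2: quad split into two triangles
            int a = inside[0], b = inside[1], c0 = outv[0], d0 = outv[1];
            interp_point(pc[tv[a]], pc[tv[c0]], fc[tv[a]], fc[tv[c0]], level, q[0]);
            interp_point(pc[tv[a]], pc[tv[d0]], fc[tv[a]], fc[tv[d0]], level, q[1]);
            interp_point(pc[tv[b]], pc[tv[d0]], fc[tv[b]], fc[tv[d0]], level, q[2]);
            interp_point(pc[tv[b]], pc[tv[c0]], fc[tv[b]], fc[tv[c0]], level, q[3]);
            double ref[3];
            for (int i = 0; i < 3; ++i) ref[i] = 0.5 * (pc[tv[a]][i] + pc[tv[b]][i]);
            add_triangle(q[0], q[1], q[2], ref, area, vol);
            add_triangle(q[0], q[2], q[3], ref, area, vol);
          }
        }
      }
  return NumericVector::create(area, vol);
}
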