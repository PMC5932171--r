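#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cone membership and vote accumulation kernels.
//
// Conventions shared with the R layer (cone_contains / cone_bounding_box):
//  * lattice coordinates are 0-based here; the R wrappers convert from
//    1-based array indices before calling in and back after.
//  * arrays are column-major with the first axis (x) varying fastest, so
//    linear index = x + nx*(y + ny*z); "first in storage order" is the
//    deterministic tie-break everywhere.
//  * all distances/angles are evaluated in physical space: lattice offsets
//    are multiplied per-axis by `spacing` (micrometers per pixel) before any
//    norm or dot product, so anisotropic stacks behave like resampled
//    isotropic ones.
//  * membership is strict on both tests: angle(p - t, dir) < phi/2 and
//    |p - t| < r, written as dot > 0 && dot*dot > cos^2(phi/2) * |q|^2
//    (valid because phi <= pi/2 implies cos(phi/2) > 0).  The R predicate
//    uses the identical expression so the two layers never disagree.

// Extent of the cone+cap solid along +axis when the cosine of the angle
// between the cone direction and +axis is `ca`.  The solid is a spherical
// sector (convex), so the extreme along any direction e is r*cos(theta-phi/2)
// clamped to [0, r]: r when the axis lies inside the aperture, 0 when the
// whole cap points away (the apex is then the extreme).
static inline double sector_extent(double ca, double r, double chalf, double shalf) {
  if (ca >= chalf) return r;                    // axis inside the half-aperture
  double sa = std::sqrt(std::max(0.0, 1.0 - ca * ca));
  double cam = ca * chalf + sa * shalf;         // cos(theta - phi/2)
  return cam > 0.0 ? r * cam : 0.0;
}

struct ConeBox {
  int lo[3];
  int hi[3];
  bool empty;
};

// Axis-aligned lattice bounding box (0-based, clipped) of the vote cone of a
// voter at integer site t with unit physical direction u.
static inline ConeBox cone_box(const double *t, const double *u, double r,
                               double chalf, double shalf, const int *dims,
                               const double *sp, int nd) {
  ConeBox b;
  b.empty = false;
  for (int a = 0; a < nd; ++a) {
    double epos = sector_extent(u[a], r, chalf, shalf);
    double eneg = sector_extent(-u[a], r, chalf, shalf);
    int lo = (int)std::ceil(t[a] - eneg / sp[a] - 1e-9);
    int hi = (int)std::floor(t[a] + epos / sp[a] + 1e-9);
    if (lo < 0) lo = 0;
    if (hi > dims[a] - 1) hi = dims[a] - 1;
    if (lo > hi) b.empty = true;
    b.lo[a] = lo;
    b.hi[a] = hi;
  }
  return b;
}

static void get_dims(const IntegerVector &dims, int *d, int &nd) {
  nd = dims.size();
  d[0] = dims[0];
  d[1] = dims[1];
  d[2] = nd == 3 ? dims[2] : 1;
}

// Cast votes: every site with magnitude > 0 and a finite direction adds its
// magnitude to V at every lattice site inside its cone.  Returns V with an
// attribute "mass" holding sum_t M(t) * |members(t)| accumulated per voter
// (the bookkeeping identity checked against sum(V)).
// [[Rcpp::export]]
NumericVector cpp_cast_votes(NumericVector mag, NumericMatrix dir,
                             IntegerVector dims, NumericVector spacing,
                             double r, double phi) {
  int d[3], nd;
  get_dims(dims, d, nd);
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  double sp[3] = {spacing[0], spacing[1], nd == 3 ? spacing[2] : 1.0};
  const double chalf = std::cos(phi / 2.0), shalf = std::sin(phi / 2.0);
  const double c2 = chalf * chalf, r2 = r * r;
  NumericVector V(nvox);
  long double mass = 0.0L;

  for (R_xlen_t v = 0; v < nvox; ++v) {
    double m = mag[v];
    if (!(m > 0.0)) continue;
    double u[3] = {dir(v, 0), dir(v, 1), nd == 3 ? dir(v, 2) : 0.0};
    if (!R_finite(u[0])) continue;
    double t[3];
    t[0] = (double)(v % nx);
    t[1] = (double)((v / nx) % ny);
    t[2] = (double)(v / ((R_xlen_t)nx * ny));
    ConeBox b = cone_box(t, u, r, chalf, shalf, d, sp, nd);
    if (b.empty) continue;
    long cnt = 0;
    int z0 = nd == 3 ? b.lo[2] : 0, z1 = nd == 3 ? b.hi[2] : 0;
    for (int z = z0; z <= z1; ++z) {
      double qz = nd == 3 ? (z - t[2]) * sp[2] : 0.0;
      for (int y = b.lo[1]; y <= b.hi[1]; ++y) {
        double qy = (y - t[1]) * sp[1];
        R_xlen_t rowbase = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = b.lo[0]; x <= b.hi[0]; ++x) {
          double qx = (x - t[0]) * sp[0];
          double d2 = qx * qx + qy * qy + qz * qz;
          if (!(d2 > 0.0) || d2 >= r2) continue;
          double dot = qx * u[0] + qy * u[1] + qz * u[2];
          if (dot > 0.0 && dot * dot > c2 * d2) {
            V[rowbase + x] += m;
            ++cnt;
          }
        }
      }
    }
    mass += (long double)m * cnt;
  }
  V.attr("mass") = (double)mass;
  return V;
}

// Direction update: each voter re-orients toward the maximum of V inside its
// cone.  Ties take the first site in storage order (strict > while scanning
// in increasing linear index).  Voters with an empty cone or an all-zero
// cone keep their previous direction.  Magnitudes are untouched.
// [[Rcpp::export]]
NumericMatrix cpp_update_directions(NumericVector mag, NumericMatrix dir,
                                    NumericVector V, IntegerVector dims,
                                    NumericVector spacing, double r,
                                    double phi) {
  int d[3], nd;
  get_dims(dims, d, nd);
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  double sp[3] = {spacing[0], spacing[1], nd == 3 ? spacing[2] : 1.0};
  const double chalf = std::cos(phi / 2.0), shalf = std::sin(phi / 2.0);
  const double c2 = chalf * chalf, r2 = r * r;
  NumericMatrix out = clone(dir);

  for (R_xlen_t v = 0; v < nvox; ++v) {
    double m = mag[v];
    if (!(m > 0.0)) continue;
    double u[3] = {dir(v, 0), dir(v, 1), nd == 3 ? dir(v, 2) : 0.0};
    if (!R_finite(u[0])) continue;
    double t[3];
    t[0] = (double)(v % nx);
    t[1] = (double)((v / nx) % ny);
    t[2] = (double)(v / ((R_xlen_t)nx * ny));
    ConeBox b = cone_box(t, u, r, chalf, shalf, d, sp, nd);
    if (b.empty) continue;
    double best = 0.0;
    R_xlen_t bestidx = -1;
    int z0 = nd == 3 ? b.lo[2] : 0, z1 = nd == 3 ? b.hi[2] : 0;
    for (int z = z0; z <= z1; ++z) {
      double qz = nd == 3 ? (z - t[2]) * sp[2] : 0.0;
      for (int y = b.lo[1]; y <= b.hi[1]; ++y) {
        double qy = (y - t[1]) * sp[1];
        R_xlen_t rowbase = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = b.lo[0]; x <= b.hi[0]; ++x) {
          double qx = (x - t[0]) * sp[0];
          double d2 = qx * qx + qy * qy + qz * qz;
          if (!(d2 > 0.0) || d2 >= r2) continue;
          double dot = qx * u[0] + qy * u[1] + qz * u[2];
          if (dot > 0.0 && dot * dot > c2 * d2) {
            double s = V[rowbase + x];
            if (s > best) {
              best = s;
              bestidx = rowbase + x;
            }
          }
        }
      }
    }
    if (bestidx >= 0) {
      double p[3];
      p[0] = (double)(bestidx % nx);
      p[1] = (double)((bestidx / nx) % ny);
      p[2] = (double)(bestidx / ((R_xlen_t)nx * ny));
      double q[3] = {0, 0, 0};
      double n2 = 0.0;
      for (int a = 0; a < nd; ++a) {
        q[a] = (p[a] - t[a]) * sp[a];
        n2 += q[a] * q[a];
      }
      double nrm = std::sqrt(n2);
      for (int a = 0; a < nd; ++a) out(v, a) = q[a] / nrm;
    }
  }
  return out;
}

// Separable sliding box maximum with per-axis integer half-widths; used by
// the local-maxima stencil.  Naive O(n*w) per axis: windows are small.
// [[Rcpp::export]]
NumericVector cpp_box_max(NumericVector values, IntegerVector dims,
                          IntegerVector halfw) {
  int d[3], nd;
  get_dims(dims, d, nd);
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(values);
  int w[3] = {halfw[0], halfw[1], nd == 3 ? halfw[2] : 0};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int a = 0; a < nd; ++a) {
    if (w[a] <= 0) continue;
    NumericVector nxt(nvox);
    int n = d[a];
    for (R_xlen_t v = 0; v < nvox; ++v) {
      int ca;
      if (a == 0)
        ca = (int)(v % nx);
      else if (a == 1)
        ca = (int)((v / nx) % ny);
      else
        ca = (int)(v / ((R_xlen_t)nx * ny));
      int j0 = ca - w[a] < 0 ? 0 : ca - w[a];
      int j1 = ca + w[a] > n - 1 ? n - 1 : ca + w[a];
      double mx = R_NegInf;
      R_xlen_t base = v - (R_xlen_t)ca * stride[a];
      for (int j = j0; j <= j1; ++j) {
        double s = cur[base + (R_xlen_t)j * stride[a]];
        if (s > mx) mx = s;
      }
      nxt[v] = mx;
    }
    cur = nxt;
  }
  return cur;
}
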