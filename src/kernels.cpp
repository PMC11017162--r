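// Low-level kernels: Kaiser-Bessel gridding (NUFFT spread/interp),
// trilinear pull-back warping with analytic gradients, multiresolution
// hash encoding forward/backward, and separable Gaussian smoothing /
// trilinear resampling used by the demons registration.
//
// Conventions shared with the R layer:
//   * volumes are column-major R arrays, dims (nx, ny, nz), voxel index
//     space is 0-based, voxel-centred;
//   * displacement fields passed to the warp are in VOXEL units
//     (converted from mm on the R side);
//   * NUFFT sample coordinates arrive in oversampled-grid units
//     u = nu * ng (nu in cycles/voxel), wrapped periodically.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Kaiser-Bessel kernel helpers
// ---------------------------------------------------------------------------

// Modified Bessel function of the first kind, order 0 (Abramowitz-Stegun
// polynomial approximations; adequate well beyond the beta range used here).
static double bessel_i0(double x) {
  double ax = std::fabs(x);
  if (ax < 3.75) {
    double t = x / 3.75;
    t *= t;
    return 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
           t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
  }
  double t = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
          t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
          t * (-0.01647633 + t * 0.00392377))))))));
}

// KB kernel on grid-index offsets, support |t| < w/2.
static inline double kb_weight(double t, double half_w, double beta, double i0b) {
  double r = t / half_w;
  double a = 1.0 - r * r;
  if (a <= 0.0) return 0.0;
  return bessel_i0(beta * std::sqrt(a)) / i0b;
}

// Continuous Fourier transform of the KB kernel, evaluated at s cycles per
// grid index; used for deapodization.  Handles the oscillatory branch.
// [[Rcpp::export]]
NumericVector kb_apodization(NumericVector s, double width, double beta) {
  int n = s.size();
  NumericVector out(n);
  double i0b = bessel_i0(beta);
  for (int i = 0; i < n; ++i) {
    double arg = M_PI * width * s[i];
    double d2 = beta * beta - arg * arg;
    double val;
    if (d2 > 0) {
      double d = std::sqrt(d2);
      val = (d < 1e-12) ? 1.0 : std::sinh(d) / d;
    } else {
      double d = std::sqrt(-d2);
      val = (d < 1e-12) ? 1.0 : std::sin(d) / d;
    }
    out[i] = width * val / i0b;
  }
  return out;
}

static inline int wrap_idx(int m, int ng) {
  m %= ng;
  return m < 0 ? m + ng : m;
}

// Interpolate oversampled-grid spectrum G (complex, dims ngd) at sample
// coordinates U (m x 3, grid units, may be negative / unwrapped).
// [[Rcpp::export]]
ComplexVector kb_interp(ComplexVector G, IntegerVector ngd, NumericMatrix U,
                        double width, NumericVector beta) {
  int m = U.nrow();
  int ngx = ngd[0], ngy = ngd[1], ngz = ngd[2];
  int w = (int)width;
  double half_w = width / 2.0;
  double i0x = bessel_i0(beta[0]), i0y = bessel_i0(beta[1]), i0z = bessel_i0(beta[2]);
  ComplexVector out(m);
  std::vector<double> wx(w), wy(w), wz(w);
  std::vector<int> ix(w), iy(w), iz(w);
  for (int j = 0; j < m; ++j) {
    double ux = U(j, 0), uy = U(j, 1), uz = U(j, 2);
    int mx0 = (int)std::ceil(ux - half_w);
    int my0 = (int)std::ceil(uy - half_w);
    int mz0 = (int)std::ceil(uz - half_w);
    for (int a = 0; a < w; ++a) {
      wx[a] = kb_weight(mx0 + a - ux, half_w, beta[0], i0x);
      wy[a] = kb_weight(my0 + a - uy, half_w, beta[1], i0y);
      wz[a] = kb_weight(mz0 + a - uz, half_w, beta[2], i0z);
      ix[a] = wrap_idx(mx0 + a, ngx);
      iy[a] = wrap_idx(my0 + a, ngy);
      iz[a] = wrap_idx(mz0 + a, ngz);
    }
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < w; ++c) {
      if (wz[c] == 0.0) continue;
      for (int b = 0; b < w; ++b) {
        double wyz = wy[b] * wz[c];
        if (wyz == 0.0) continue;
        R_xlen_t base = (R_xlen_t)iy[b] * ngx + (R_xlen_t)iz[c] * ngx * ngy;
        for (int a = 0; a < w; ++a) {
          double wt = wx[a] * wyz;
          if (wt == 0.0) continue;
          Rcomplex g = G[base + ix[a]];
          sr += wt * g.r;
          si += wt * g.i;
        }
      }
    }
    out[j].r = sr;
    out[j].i = si;
  }
  return out;
}

// Adjoint of kb_interp: spread samples y onto the oversampled grid.
// [[Rcpp::export]]
ComplexVector kb_spread(ComplexVector y, IntegerVector ngd, NumericMatrix U,
                        double width, NumericVector beta) {
  int m = U.nrow();
  int ngx = ngd[0], ngy = ngd[1], ngz = ngd[2];
  int w = (int)width;
  double half_w = width / 2.0;
  double i0x = bessel_i0(beta[0]), i0y = bessel_i0(beta[1]), i0z = bessel_i0(beta[2]);
  ComplexVector G((R_xlen_t)ngx * ngy * ngz);
  std::vector<double> wx(w), wy(w), wz(w);
  std::vector<int> ix(w), iy(w), iz(w);
  for (int j = 0; j < m; ++j) {
    double ux = U(j, 0), uy = U(j, 1), uz = U(j, 2);
    int mx0 = (int)std::ceil(ux - half_w);
    int my0 = (int)std::ceil(uy - half_w);
    int mz0 = (int)std::ceil(uz - half_w);
    for (int a = 0; a < w; ++a) {
      wx[a] = kb_weight(mx0 + a - ux, half_w, beta[0], i0x);
      wy[a] = kb_weight(my0 + a - uy, half_w, beta[1], i0y);
      wz[a] = kb_weight(mz0 + a - uz, half_w, beta[2], i0z);
      ix[a] = wrap_idx(mx0 + a, ngx);
      iy[a] = wrap_idx(my0 + a, ngy);
      iz[a] = wrap_idx(mz0 + a, ngz);
    }
    double yr = y[j].r, yi = y[j].i;
    for (int c = 0; c < w; ++c) {
      if (wz[c] == 0.0) continue;
      for (int b = 0; b < w; ++b) {
        double wyz = wy[b] * wz[c];
        if (wyz == 0.0) continue;
        R_xlen_t base = (R_xlen_t)iy[b] * ngx + (R_xlen_t)iz[c] * ngx * ngy;
        for (int a = 0; a < w; ++a) {
          double wt = wx[a] * wyz;
          if (wt == 0.0) continue;
          G[base + ix[a]].r += wt * yr;
          G[base + ix[a]].i += wt * yi;
        }
      }
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Trilinear pull-back warping (complex volumes), forward and backward
// ---------------------------------------------------------------------------

// out(x) = ref(x + d(x)), zero outside the grid; d in voxel units.
// [[Rcpp::export]]
ComplexVector warp_trilinear(ComplexVector ref, IntegerVector dims,
                             NumericMatrix dvf_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  ComplexVector out(n);
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x, ++v) {
    double px = x + dvf_vox(v, 0);
    double py = y + dvf_vox(v, 1);
    double pz = z + dvf_vox(v, 2);
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    double sr = 0.0, si = 0.0;
    for (int cz = 0; cz < 2; ++cz) {
      int zz = z0 + cz;
      if (zz < 0 || zz >= nz) continue;
      double wz = cz ? fz : 1.0 - fz;
      for (int cy = 0; cy < 2; ++cy) {
        int yy = y0 + cy;
        if (yy < 0 || yy >= ny) continue;
        double wyz = (cy ? fy : 1.0 - fy) * wz;
        for (int cx = 0; cx < 2; ++cx) {
          int xx = x0 + cx;
          if (xx < 0 || xx >= nx) continue;
          double wt = (cx ? fx : 1.0 - fx) * wyz;
          Rcomplex r = ref[(R_xlen_t)xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny];
          sr += wt * r.r;
          si += wt * r.i;
        }
      }
    }
    out[v].r = sr;
    out[v].i = si;
  }
  return out;
}

// Backward pass of warp_trilinear.  gr/gi: dL/d(Re out), dL/d(Im out).
// Returns list(grad_ref = complex vector whose re/im parts are dL/dRe(ref),
// dL/dIm(ref), grad_dvf = n x 3 matrix, dL/d d (voxel units)).
// [[Rcpp::export]]
List warp_trilinear_backward(NumericVector gr, NumericVector gi,
                             ComplexVector ref, IntegerVector dims,
                             NumericMatrix dvf_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  ComplexVector gref(n);
  NumericMatrix gdvf(n, 3);
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x, ++v) {
    double gvr = gr[v], gvi = gi[v];
    if (gvr == 0.0 && gvi == 0.0) continue;
    double px = x + dvf_vox(v, 0);
    double py = y + dvf_vox(v, 1);
    double pz = z + dvf_vox(v, 2);
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    double gdx = 0.0, gdy = 0.0, gdz = 0.0;
    for (int cz = 0; cz < 2; ++cz) {
      int zz = z0 + cz;
      if (zz < 0 || zz >= nz) continue;
      double wz = cz ? fz : 1.0 - fz;
      double dz = cz ? 1.0 : -1.0;
      for (int cy = 0; cy < 2; ++cy) {
        int yy = y0 + cy;
        if (yy < 0 || yy >= ny) continue;
        double wy = cy ? fy : 1.0 - fy;
        double dy = cy ? 1.0 : -1.0;
        for (int cx = 0; cx < 2; ++cx) {
          int xx = x0 + cx;
          if (xx < 0 || xx >= nx) continue;
          double wx = cx ? fx : 1.0 - fx;
          double dx = cx ? 1.0 : -1.0;
          R_xlen_t ci = (R_xlen_t)xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny;
          double wt = wx * wy * wz;
          gref[ci].r += wt * gvr;
          gref[ci].i += wt * gvi;
          Rcomplex r = ref[ci];
          double gdot = gvr * r.r + gvi * r.i;
          gdx += dx * wy * wz * gdot;
          gdy += wx * dy * wz * gdot;
          gdz += wx * wy * dz * gdot;
        }
      }
    }
    gdvf(v, 0) = gdx;
    gdvf(v, 1) = gdy;
    gdvf(v, 2) = gdz;
  }
  return List::create(_["grad_ref"] = gref, _["grad_dvf"] = gdvf);
}

// ---------------------------------------------------------------------------
// Multiresolution hash encoding
// ---------------------------------------------------------------------------

static const uint32_t HASH_PRIMES[3] = {1u, 2654435761u, 805459861u};

// Vertex -> table row (0-based).  Direct (collision-free) indexing when the
// level's vertex grid fits in the table, spatial XOR hash otherwise.
static inline uint32_t vertex_index(const int *v, int d, int nres,
                                    uint32_t tsize, bool direct) {
  if (direct) {
    uint32_t idx = 0;
    for (int k = d - 1; k >= 0; --k) idx = idx * (uint32_t)(nres + 1) + (uint32_t)v[k];
    return idx;
  }
  uint32_t h = 0;
  for (int k = 0; k < d; ++k) h ^= (uint32_t)v[k] * HASH_PRIMES[k];
  return h & (tsize - 1u);
}

// [[Rcpp::export]]
IntegerVector hash_index_cpp(IntegerMatrix vertices, int nres, int tsize) {
  int m = vertices.nrow(), d = vertices.ncol();
  double nvert = std::pow((double)(nres + 1), d);
  bool direct = nvert <= (double)tsize;
  IntegerVector out(m);
  std::vector<int> v(d);
  for (int j = 0; j < m; ++j) {
    for (int k = 0; k < d; ++k) v[k] = vertices(j, k);
    out[j] = (int)vertex_index(v.data(), d, nres, (uint32_t)tsize, direct);
  }
  return out;
}

// Forward multilevel encoding.  coords: n x d in [-1, 1] (clamped here);
// tables: list of T_l x F matrices; res: per-level resolutions N_l.
// Returns n x (L*F) feature matrix.
// [[Rcpp::export]]
NumericMatrix hash_encode_cpp(NumericMatrix coords, List tables,
                              IntegerVector res, int tsize, int nfeat) {
  int n = coords.nrow(), d = coords.ncol(), L = res.size();
  NumericMatrix out(n, L * nfeat);
  int ncorner = 1 << d;
  std::vector<int> v0(d), v(d);
  std::vector<double> fr(d);
  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    int nres = res[l];
    bool direct = std::pow((double)(nres + 1), d) <= (double)tsize;
    for (int j = 0; j < n; ++j) {
      for (int k = 0; k < d; ++k) {
        double c = coords(j, k);
        if (c < -1.0) c = -1.0;
        if (c > 1.0) c = 1.0;
        double x = (c + 1.0) * 0.5 * nres;   // [0, N_l]
        int i0 = (int)std::floor(x);
        if (i0 > nres - 1) i0 = nres - 1;    // keep x in cell [N_l-1, N_l]
        if (i0 < 0) i0 = 0;
        v0[k] = i0;
        fr[k] = x - i0;
      }
      for (int c = 0; c < ncorner; ++c) {
        double wt = 1.0;
        for (int k = 0; k < d; ++k) {
          int bit = (c >> k) & 1;
          v[k] = v0[k] + bit;
          wt *= bit ? fr[k] : 1.0 - fr[k];
        }
        if (wt == 0.0) continue;
        uint32_t row = vertex_index(v.data(), d, nres, (uint32_t)tsize, direct);
        for (int f = 0; f < nfeat; ++f)
          out(j, l * nfeat + f) += wt * tab(row, f);
      }
    }
  }
  return out;
}

// Backward: scatter dL/dfeatures into per-level table gradients.
// [[Rcpp::export]]
List hash_encode_backward_cpp(NumericMatrix coords, NumericMatrix gfeat,
                              List tables, IntegerVector res, int tsize,
                              int nfeat) {
  int n = coords.nrow(), d = coords.ncol(), L = res.size();
  int ncorner = 1 << d;
  List grads(L);
  std::vector<int> v0(d), v(d);
  std::vector<double> fr(d);
  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    NumericMatrix g(tab.nrow(), nfeat);
    int nres = res[l];
    bool direct = std::pow((double)(nres + 1), d) <= (double)tsize;
    for (int j = 0; j < n; ++j) {
      bool any = false;
      for (int f = 0; f < nfeat; ++f)
        if (gfeat(j, l * nfeat + f) != 0.0) { any = true; break; }
      if (!any) continue;
      for (int k = 0; k < d; ++k) {
        double c = coords(j, k);
        if (c < -1.0) c = -1.0;
        if (c > 1.0) c = 1.0;
        double x = (c + 1.0) * 0.5 * nres;
        int i0 = (int)std::floor(x);
        if (i0 > nres - 1) i0 = nres - 1;
        if (i0 < 0) i0 = 0;
        v0[k] = i0;
        fr[k] = x - i0;
      }
      for (int c = 0; c < ncorner; ++c) {
        double wt = 1.0;
        for (int k = 0; k < d; ++k) {
          int bit = (c >> k) & 1;
          v[k] = v0[k] + bit;
          wt *= bit ? fr[k] : 1.0 - fr[k];
        }
        if (wt == 0.0) continue;
        uint32_t row = vertex_index(v.data(), d, nres, (uint32_t)tsize, direct);
        for (int f = 0; f < nfeat; ++f)
          g(row, f) += wt * gfeat(j, l * nfeat + f);
      }
    }
    grads[l] = g;
  }
  return grads;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing and trilinear resampling (registration)
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double> &buf, NumericVector &vol,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto &kk : k) kk /= s;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)a * nx + (R_xlen_t)b * nx * ny;
      else if (axis == 1) base = (R_xlen_t)a + (R_xlen_t)b * nx * ny;
      else base = (R_xlen_t)a + (R_xlen_t)b * nx;
      for (int i = 0; i < len; ++i) buf[i] = vol[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t) {
          int ii = i + t;
          if (ii < 0) ii = 0;               // replicate borders
          if (ii >= len) ii = len - 1;
          acc += k[t + rad] * buf[ii];
        }
        vol[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussian_smooth3(NumericVector vol, IntegerVector dims, double sigma) {
  NumericVector out = clone(vol);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> buf((size_t)std::max(nx, std::max(ny, nz)));
  smooth_axis(buf, out, nx, ny, nz, 0, sigma);
  smooth_axis(buf, out, nx, ny, nz, 1, sigma);
  smooth_axis(buf, out, nx, ny, nz, 2, sigma);
  return out;
}

// Trilinear resize of a real volume to new dims (voxel-centre aligned,
// border-clamped).
// [[Rcpp::export]]
NumericVector resize_trilinear(NumericVector vol, IntegerVector dims,
                               IntegerVector newdims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = newdims[0], my = newdims[1], mz = newdims[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  double sx = (double)nx / mx, sy = (double)ny / my, sz = (double)nz / mz;
  R_xlen_t v = 0;
  for (int z = 0; z < mz; ++z)
  for (int y = 0; y < my; ++y)
  for (int x = 0; x < mx; ++x, ++v) {
    double px = (x + 0.5) * sx - 0.5;
    double py = (y + 0.5) * sy - 0.5;
    double pz = (z + 0.5) * sz - 0.5;
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    double acc = 0.0;
    for (int cz = 0; cz < 2; ++cz) {
      int zz = std::min(std::max(z0 + cz, 0), nz - 1);
      double wz = cz ? fz : 1.0 - fz;
      for (int cy = 0; cy < 2; ++cy) {
        int yy = std::min(std::max(y0 + cy, 0), ny - 1);
        double wy = cy ? fy : 1.0 - fy;
        for (int cx = 0; cx < 2; ++cx) {
          int xx = std::min(std::max(x0 + cx, 0), nx - 1);
          double wx = cx ? fx : 1.0 - fx;
          acc += wx * wy * wz * vol[(R_xlen_t)xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny];
        }
      }
    }
    out[v] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Precomputed-topology hash encoding (fixed coordinate sets)
// ---------------------------------------------------------------------------

// For a fixed coordinate set, precompute per-level corner rows and
// interpolation weights once; the per-epoch forward/backward then reduce
// to gathers/scatters.
// [[Rcpp::export]]
List hash_precompute_cpp(NumericMatrix coords, IntegerVector res, int tsize) {
  int n = coords.nrow(), d = coords.ncol(), L = res.size();
  int ncorner = 1 << d;
  IntegerMatrix idx(n, L * ncorner);
  NumericMatrix wts(n, L * ncorner);
  std::vector<int> v0(d), v(d);
  std::vector<double> fr(d);
  for (int l = 0; l < L; ++l) {
    int nres = res[l];
    bool direct = std::pow((double)(nres + 1), d) <= (double)tsize;
    for (int j = 0; j < n; ++j) {
      for (int k = 0; k < d; ++k) {
        double c = coords(j, k);
        if (c < -1.0) c = -1.0;
        if (c > 1.0) c = 1.0;
        double x = (c + 1.0) * 0.5 * nres;
        int i0 = (int)std::floor(x);
        if (i0 > nres - 1) i0 = nres - 1;
        if (i0 < 0) i0 = 0;
        v0[k] = i0;
        fr[k] = x - i0;
      }
      for (int c = 0; c < ncorner; ++c) {
        double wt = 1.0;
        for (int k = 0; k < d; ++k) {
          int bit = (c >> k) & 1;
          v[k] = v0[k] + bit;
          wt *= bit ? fr[k] : 1.0 - fr[k];
        }
        idx(j, l * ncorner + c) = (int)vertex_index(v.data(), d, nres,
                                                   (uint32_t)tsize, direct);
        wts(j, l * ncorner + c) = wt;
      }
    }
  }
  return List::create(_["idx"] = idx, _["wts"] = wts,
                      _["ncorner"] = ncorner, _["n_levels"] = L);
}

// [[Rcpp::export]]
NumericMatrix hash_encode_pre_cpp(List tables, IntegerMatrix idx,
                                  NumericMatrix wts, int ncorner, int nfeat) {
  int n = idx.nrow(), L = idx.ncol() / ncorner;
  NumericMatrix out(n, L * nfeat);
  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    const double *tp = tab.begin();
    int trows = tab.nrow();
    for (int f = 0; f < nfeat; ++f) {
      const double *col = tp + (R_xlen_t)f * trows;
      double *ocol = out.begin() + (R_xlen_t)(l * nfeat + f) * n;
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        const int *ij = idx.begin() + j;
        const double *wj = wts.begin() + j;
        R_xlen_t base = (R_xlen_t)l * ncorner * n;
        for (int c = 0; c < ncorner; ++c) {
          R_xlen_t off = base + (R_xlen_t)c * n;
          acc += wj[off] * col[ij[off]];
        }
        ocol[j] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List hash_encode_backward_pre_cpp(List tables, IntegerMatrix idx,
                                  NumericMatrix wts, NumericMatrix gfeat,
                                  int ncorner, int nfeat) {
  int n = idx.nrow(), L = idx.ncol() / ncorner;
  List grads(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    int trows = tab.nrow();
    NumericMatrix g(trows, nfeat);
    for (int f = 0; f < nfeat; ++f) {
      double *gcol = g.begin() + (R_xlen_t)f * trows;
      const double *gf = gfeat.begin() + (R_xlen_t)(l * nfeat + f) * n;
      for (int j = 0; j < n; ++j) {
        double gv = gf[j];
        if (gv == 0.0) continue;
        const int *ij = idx.begin() + j;
        const double *wj = wts.begin() + j;
        R_xlen_t base = (R_xlen_t)l * ncorner * n;
        for (int c = 0; c < ncorner; ++c) {
          R_xlen_t off = base + (R_xlen_t)c * n;
          gcol[ij[off]] += wj[off] * gv;
        }
      }
    }
    grads[l] = g;
  }
  return grads;
}

// ---------------------------------------------------------------------------
// NUFFT grid embedding / cropping (hot-path helpers)
// ---------------------------------------------------------------------------

// Place vol * deapod into the oversampled grid at wrapped slots emb
// (1-based per-axis index vectors, length = image dims).
// [[Rcpp::export]]
ComplexVector embed_deapod(ComplexVector vol, NumericVector deapod,
                           IntegerVector dims, IntegerVector ngd,
                           IntegerVector ex, IntegerVector ey,
                           IntegerVector ez) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  ComplexVector G((R_xlen_t)ngd[0] * ngd[1] * ngd[2]);
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z) {
    R_xlen_t oz = (R_xlen_t)(ez[z] - 1) * ngd[0] * ngd[1];
    for (int y = 0; y < ny; ++y) {
      R_xlen_t oy = oz + (R_xlen_t)(ey[y] - 1) * ngd[0];
      for (int x = 0; x < nx; ++x, ++v) {
        double d = deapod[v];
        R_xlen_t o = oy + (ex[x] - 1);
        G[o].r = vol[v].r * d;
        G[o].i = vol[v].i * d;
      }
    }
  }
  return G;
}

// Extract the image-grid samples from the oversampled grid and multiply
// by the deapodization (adjoint of embed_deapod).
// [[Rcpp::export]]
ComplexVector crop_deapod(ComplexVector G, NumericVector deapod,
                          IntegerVector dims, IntegerVector ngd,
                          IntegerVector ex, IntegerVector ey,
                          IntegerVector ez) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  ComplexVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z) {
    R_xlen_t oz = (R_xlen_t)(ez[z] - 1) * ngd[0] * ngd[1];
    for (int y = 0; y < ny; ++y) {
      R_xlen_t oy = oz + (R_xlen_t)(ey[y] - 1) * ngd[0];
      for (int x = 0; x < nx; ++x, ++v) {
        double d = deapod[v];
        R_xlen_t o = oy + (ex[x] - 1);
        out[v].r = G[o].r * d;
        out[v].i = G[o].i * d;
      }
    }
  }
  return out;
}
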