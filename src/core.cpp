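// Compiled kernels: volume resampling under an affine voxel map, the masked
// NCC metric used by the registration optimizer, separable Gaussian smoothing,
// 2x block-mean downsampling, and patchwise Marchenko-Pastur PCA denoising.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_linear(const double *v, int nx, int ny, int nz,
                                   double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Catmull-Rom weights for fractional offset t, taps at -1,0,1,2
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline double sample_cubic(const double *v, int nx, int ny, int nz,
                                  double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cr_weights(x - x0, wx);
  cr_weights(y - y0, wy);
  cr_weights(z - z0, wz);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double acc = 0.0;
  for (int kz = -1; kz <= 2; ++kz) {
    int zz = std::min(std::max(z0 + kz, 0), nz - 1);
    double az = 0.0;
    for (int ky = -1; ky <= 2; ++ky) {
      int yy = std::min(std::max(y0 + ky, 0), ny - 1);
      double ay = 0.0;
      const double *row = v + yy * sy + zz * sz;
      for (int kx = -1; kx <= 2; ++kx) {
        int xx = std::min(std::max(x0 + kx, 0), nx - 1);
        ay += wx[kx + 1] * row[xx];
      }
      az += wy[ky + 1] * ay;
    }
    acc += wz[kz + 1] * az;
  }
  return acc;
}

// Resample a 3-D volume: out(i,j,k) = in(M %*% c(i,j,k,1)) in 0-based voxel
// coordinates. M is the full voxel-to-voxel map (output grid -> input grid).
// interp: 0 = trilinear, 1 = cubic spline.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, int interp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *v = vol.begin();
  double *o = out.begin();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = m00 * i + m01 * j + m02 * k + m03;
        double y = m10 * i + m11 * j + m12 * k + m13;
        double z = m20 * i + m21 * j + m22 * k + m23;
        o[idx] = interp == 0 ? sample_linear(v, nx, ny, nz, x, y, z)
                             : sample_cubic(v, nx, ny, nz, x, y, z);
      }
  return out;
}

// Trilinear samples of a volume at 0-based voxel coordinates (n x 3).
// [[Rcpp::export(name = ".sample_points_cpp")]]
NumericVector sample_points_cpp(NumericVector vol, IntegerVector dim,
                                NumericMatrix coords) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = vol.begin();
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = sample_linear(v, nx, ny, nz, coords(t, 0), coords(t, 1),
                           coords(t, 2));
  return out;
}

// Negative NCC between fixed values at mask points and the moving volume
// sampled at M-transformed mask coordinates (0-based voxel coords, n x 3).
// [[Rcpp::export(name = ".ncc_points_cpp")]]
double ncc_points_cpp(NumericVector moving, IntegerVector dim,
                      NumericMatrix coords, NumericVector fixedvals,
                      NumericMatrix M) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = moving.begin();
  R_xlen_t n = coords.nrow();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  R_xlen_t inside = 0;
  const double *cx = &coords(0, 0), *cy = &coords(0, 1), *cz = &coords(0, 2);
  for (R_xlen_t t = 0; t < n; ++t) {
    double i = cx[t], j = cy[t], k = cz[t];
    double x = m00 * i + m01 * j + m02 * k + m03;
    double y = m10 * i + m11 * j + m12 * k + m13;
    double z = m20 * i + m21 * j + m22 * k + m23;
    if (x >= 0 && y >= 0 && z >= 0 && x <= nx - 1.0 && y <= ny - 1.0 &&
        z <= nz - 1.0)
      ++inside;
    double a = sample_linear(v, nx, ny, nz, x, y, z);
    double b = fixedvals[t];
    sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
  }
  // overlap guard: reject transforms that push most of the mask off-field,
  // where the correlation is driven by sampling artifacts
  if (inside < 0.85 * n) return 0.0;
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  double cov = sab - sa * sb / n;
  if (va <= 0 || vb <= 0) return 0.0;
  return -cov / std::sqrt(va * vb);
}

static void smooth_axis(std::vector<double> &buf, double *v, int nx, int ny,
                        int nz, int axis, const std::vector<double> &ker) {
  int r = (int)(ker.size() - 1) / 2;
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  int dims[3] = {nx, ny, nz};
  R_xlen_t s = strides[axis];
  int n = dims[axis];
  // iterate over all lines along `axis`
  int d1 = (axis + 1) % 3, d2 = (axis + 2) % 3;
  for (int b = 0; b < dims[d2]; ++b)
    for (int a = 0; a < dims[d1]; ++a) {
      double *line0 = v + a * strides[d1] + b * strides[d2];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ii = i + t;
          if (ii < 0) ii = -ii;                  // reflect
          if (ii > n - 1) ii = 2 * (n - 1) - ii;
          acc += ker[t + r] * line0[(R_xlen_t)ii * s];
        }
        buf[i] = acc;
      }
      for (int i = 0; i < n; ++i) line0[(R_xlen_t)i * s] = buf[i];
    }
}

// In-place-style separable Gaussian smoothing, sigma in voxels.
// [[Rcpp::export(name = ".gauss_smooth3_cpp")]]
NumericVector gauss_smooth3_cpp(NumericVector vol, IntegerVector dim,
                                double sigma) {
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, tot = 0.0;
  for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-t * t / s2); tot += ker[t + r]; }
  for (auto &k : ker) k /= tot;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(buf, out.begin(), nx, ny, nz, axis, ker);
  return out;
}

// 2x2x2 block-mean downsampling (truncating odd edges).
// [[Rcpp::export(name = ".downsample2_cpp")]]
NumericVector downsample2_cpp(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *v = vol.begin();
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        const double *p = v + 2 * i + 2 * j * sy + 2 * k * sz;
        double acc = p[0] + p[1] + p[sy] + p[sy + 1] + p[sz] + p[sz + 1] +
                     p[sz + sy] + p[sz + sy + 1];
        out[idx] = acc / 8.0;
      }
  out.attr("odim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Marchenko-Pastur PCA denoising. arr: nx*ny*nz*nv array, patch side
// (2*radius+1)^3, sliding with the given stride; patch windows are clamped to
// the volume so every voxel is covered. Returns the averaged reconstruction
// and an averaged noise-sigma map.
// [[Rcpp::export(name = ".mppca_cpp")]]
List mppca_cpp(NumericVector arr, IntegerVector dim4, int radius, int stride) {
  int nx = dim4[0], ny = dim4[1], nz = dim4[2], nv = dim4[3];
  int side = 2 * radius + 1;
  if (side > nx || side > ny || side > nz)
    stop("patch larger than volume");
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double *a = arr.begin();
  NumericVector outv(nvox * nv), wsum(nvox), sigacc(nvox);
  double *o = outv.begin(), *w = wsum.begin(), *sg = sigacc.begin();
  int m = side * side * side;
  arma::mat X(m, nv), Xc(m, nv);
  arma::vec mu(nv);
  int Q = std::max(m, nv), R = std::min(m, nv);
  std::vector<R_xlen_t> lin(m);

  // patch start positions per axis (clamped, deduplicated tail)
  auto starts = [&](int n) {
    std::vector<int> s;
    for (int p = 0;; p += stride) {
      if (p + side >= n) { s.push_back(n - side); break; }
      s.push_back(p);
    }
    return s;
  };
  std::vector<int> sxs = starts(nx), sys = starts(ny), szs = starts(nz);

  for (int pz : szs)
    for (int py : sys)
      for (int px : sxs) {
        int t = 0;
        for (int k = 0; k < side; ++k)
          for (int j = 0; j < side; ++j)
            for (int i = 0; i < side; ++i, ++t)
              lin[t] = (px + i) + (R_xlen_t)(py + j) * nx +
                       (R_xlen_t)(pz + k) * nx * ny;
        for (int vv = 0; vv < nv; ++vv) {
          const double *col = a + (R_xlen_t)vv * nvox;
          double s = 0.0;
          for (int u = 0; u < m; ++u) { X(u, vv) = col[lin[u]]; s += X(u, vv); }
          mu[vv] = s / m;
        }
        Xc = X;
        Xc.each_row() -= mu.t();

        arma::vec eval;
        arma::mat evec;
        bool tall = m >= nv; // eig on the smaller Gram side
        if (tall)
          arma::eig_sym(eval, evec, arma::symmatu(Xc.t() * Xc));
        else
          arma::eig_sym(eval, evec, arma::symmatu(Xc * Xc.t()));
        // ascending eigenvalues; scale to covariance units
        arma::vec e = arma::clamp(eval, 0.0, arma::datum::inf) / Q;

        // MP criterion: largest k noise eigenvalues whose spread is
        // consistent with the MP bulk edge for aspect ratio k/Q.
        int kbest = 1;
        double sig2 = e[0], csum = 0.0;
        for (int k = 1; k <= R; ++k) {
          csum += e[k - 1];
          double s1 = csum / k;
          double s2 = (e[k - 1] - e[0]) / (4.0 * std::sqrt((double)k / Q));
          if (s2 <= s1) { kbest = k; sig2 = s1; }
        }
        int nsig = R - kbest; // retained signal components

        arma::mat Xhat;
        if (nsig <= 0) {
          Xhat.zeros(m, nv);
        } else if (nsig >= R) {
          Xhat = Xc;
        } else {
          arma::mat V = evec.cols(R - nsig, R - 1);
          if (tall)
            Xhat = (Xc * V) * V.t();
          else
            Xhat = V * (V.t() * Xc);
        }
        Xhat.each_row() += mu.t();

        double sig = std::sqrt(std::max(sig2, 0.0));
        for (int u = 0; u < m; ++u) {
          R_xlen_t li = lin[u];
          w[li] += 1.0;
          sg[li] += sig;
          for (int vv = 0; vv < nv; ++vv)
            o[li + (R_xlen_t)vv * nvox] += Xhat(u, vv);
        }
      }

  for (R_xlen_t li = 0; li < nvox; ++li) {
    double ww = w[li];
    if (ww > 0) {
      sg[li] /= ww;
      for (int vv = 0; vv < nv; ++vv) o[li + (R_xlen_t)vv * nvox] /= ww;
    } else {
      for (int vv = 0; vv < nv; ++vv)
        o[li + (R_xlen_t)vv * nvox] = a[li + (R_xlen_t)vv * nvox];
    }
  }
  return List::create(_["denoised"] = outv, _["sigma"] = sigacc);
}
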