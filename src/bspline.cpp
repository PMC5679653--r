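// Cubic B-spline free-form deformation (FFD) kernels.
//
// A transform is a lattice of control-point displacements with uniform knot
// spacing `delta` (in voxel units).  For image dimension n along an axis the
// lattice has K = ceil((n-1)/delta) spans and K+3 control points (indices
// -1 .. K+1, stored with offset +1).  Displacements are interpolated with the
// uniform cubic B-spline basis; evaluation points outside the image domain
// are clamped to the lattice support (the caller sees a clamp count).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void cubw(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// span index + local parameter for coordinate x (voxel units), K spans
static inline void span_of(double x, double delta, int K, int& i, double& t) {
  double u = x / delta;
  if (u < 0.0) u = 0.0;
  if (u > (double)K) u = (double)K;
  i = (int)std::floor(u);
  if (i > K - 1) i = K - 1;
  if (i < 0) i = 0;
  t = u - i;
}

// [[Rcpp::export]]
NumericMatrix ffd_eval_points_cpp(NumericVector coef, double delta,
                                  NumericMatrix pts, NumericVector extent) {
  IntegerVector cd = coef.attr("dim");
  const int d = cd.size() - 1;
  const int np = pts.nrow();
  NumericMatrix out(np, d);
  int nclamp = 0;
  if (d == 2) {
    const int ncx = cd[0], ncy = cd[1];
    const int Kx = ncx - 3, Ky = ncy - 3;
    double wx[4], wy[4];
    for (int q = 0; q < np; ++q) {
      double x = pts(q, 0), y = pts(q, 1);
      if (x < 0 || x > extent[0] - 1 || y < 0 || y > extent[1] - 1) ++nclamp;
      int ix, iy; double tx, ty;
      span_of(x, delta, Kx, ix, tx); cubw(tx, wx);
      span_of(y, delta, Ky, iy, ty); cubw(ty, wy);
      for (int c = 0; c < 2; ++c) {
        double s = 0.0;
        const double* cc = &coef[(size_t)c * ncx * ncy];
        for (int b = 0; b < 4; ++b) {
          const double* col = cc + (size_t)(iy + b) * ncx + ix;
          double sx = wx[0] * col[0] + wx[1] * col[1] + wx[2] * col[2] + wx[3] * col[3];
          s += wy[b] * sx;
        }
        out(q, c) = s;
      }
    }
  } else {
    const int ncx = cd[0], ncy = cd[1], ncz = cd[2];
    const int Kx = ncx - 3, Ky = ncy - 3, Kz = ncz - 3;
    double wx[4], wy[4], wz[4];
    for (int q = 0; q < np; ++q) {
      double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
      if (x < 0 || x > extent[0] - 1 || y < 0 || y > extent[1] - 1 ||
          z < 0 || z > extent[2] - 1) ++nclamp;
      int ix, iy, iz; double tx, ty, tz;
      span_of(x, delta, Kx, ix, tx); cubw(tx, wx);
      span_of(y, delta, Ky, iy, ty); cubw(ty, wy);
      span_of(z, delta, Kz, iz, tz); cubw(tz, wz);
      for (int c = 0; c < 3; ++c) {
        double s = 0.0;
        const double* cc = &coef[(size_t)c * ncx * ncy * ncz];
        for (int b3 = 0; b3 < 4; ++b3) {
          double sy = 0.0;
          for (int b2 = 0; b2 < 4; ++b2) {
            const double* col = cc + ((size_t)(iz + b3) * ncy + (iy + b2)) * ncx + ix;
            double sx = wx[0] * col[0] + wx[1] * col[1] + wx[2] * col[2] + wx[3] * col[3];
            sy += wy[b2] * sx;
          }
          s += wz[b3] * sy;
        }
        out(q, c) = s;
      }
    }
  }
  out.attr("clamped") = nclamp;
  return out;
}

// Displacement at every voxel centre (column-major voxel order).
// [[Rcpp::export]]
NumericMatrix ffd_eval_grid_cpp(NumericVector coef, double delta, IntegerVector dims) {
  IntegerVector cd = coef.attr("dim");
  const int d = cd.size() - 1;
  size_t nv = 1; for (int k = 0; k < d; ++k) nv *= dims[k];
  NumericMatrix out(nv, d);
  if (d == 2) {
    const int nx = dims[0], ny = dims[1];
    const int ncx = cd[0], ncy = cd[1];
    const int Kx = ncx - 3, Ky = ncy - 3;
    std::vector<int> ixv(nx); std::vector<double> wxv(4 * nx);
    for (int x = 0; x < nx; ++x) { double t; span_of(x, delta, Kx, ixv[x], t); cubw(t, &wxv[4 * x]); }
    double wy[4];
    size_t v = 0;
    for (int y = 0; y < ny; ++y) {
      int iy; double ty; span_of(y, delta, Ky, iy, ty); cubw(ty, wy);
      for (int x = 0; x < nx; ++x, ++v) {
        const double* wx = &wxv[4 * x]; const int ix = ixv[x];
        for (int c = 0; c < 2; ++c) {
          const double* cc = &coef[(size_t)c * ncx * ncy];
          double s = 0.0;
          for (int b = 0; b < 4; ++b) {
            const double* col = cc + (size_t)(iy + b) * ncx + ix;
            s += wy[b] * (wx[0] * col[0] + wx[1] * col[1] + wx[2] * col[2] + wx[3] * col[3]);
          }
          out(v, c) = s;
        }
      }
    }
  } else {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int ncx = cd[0], ncy = cd[1], ncz = cd[2];
    const int Kx = ncx - 3, Ky = ncy - 3, Kz = ncz - 3;
    std::vector<int> ixv(nx), iyv(ny);
    std::vector<double> wxv(4 * nx), wyv(4 * ny);
    for (int x = 0; x < nx; ++x) { double t; span_of(x, delta, Kx, ixv[x], t); cubw(t, &wxv[4 * x]); }
    for (int y = 0; y < ny; ++y) { double t; span_of(y, delta, Ky, iyv[y], t); cubw(t, &wyv[4 * y]); }
    double wz[4];
    size_t v = 0;
    for (int z = 0; z < nz; ++z) {
      int iz; double tz; span_of(z, delta, Kz, iz, tz); cubw(tz, wz);
      for (int y = 0; y < ny; ++y) {
        const double* wy = &wyv[4 * y]; const int iy = iyv[y];
        for (int x = 0; x < nx; ++x, ++v) {
          const double* wx = &wxv[4 * x]; const int ix = ixv[x];
          for (int c = 0; c < 3; ++c) {
            const double* cc = &coef[(size_t)c * ncx * ncy * ncz];
            double s = 0.0;
            for (int b3 = 0; b3 < 4; ++b3) {
              double sy = 0.0;
              for (int b2 = 0; b2 < 4; ++b2) {
                const double* col = cc + ((size_t)(iz + b3) * ncy + (iy + b2)) * ncx + ix;
                sy += wy[b2] * (wx[0] * col[0] + wx[1] * col[1] + wx[2] * col[2] + wx[3] * col[3]);
              }
              s += wz[b3] * sy;
            }
            out(v, c) = s;
          }
        }
      }
    }
  }
  return out;
}

static inline double samp2(const double* img, int nx, int ny, double x, double y) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2;
  double fx = x - x0, fy = y - y0;
  const double* p = img + (size_t)y0 * nx + x0;
  double a = p[0] * (1 - fx) + p[1] * fx;
  double b = p[nx] * (1 - fx) + p[nx + 1] * fx;
  return a * (1 - fy) + b * fy;
}

static inline double samp3(const double* img, int nx, int ny, int nz,
                           double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sxy = (size_t)nx * ny;
  const double* p = img + (size_t)z0 * sxy + (size_t)y0 * nx + x0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
  double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample img at x + disp (linear interpolation, nearest-edge border fill).
// [[Rcpp::export]]
NumericVector warp_linear_cpp(NumericVector img, IntegerVector dims, NumericMatrix disp) {
  const int d = dims.size();
  size_t nv = 1; for (int k = 0; k < d; ++k) nv *= dims[k];
  NumericVector out(nv);
  const double* im = &img[0];
  if (d == 2) {
    const int nx = dims[0], ny = dims[1];
    size_t v = 0;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++v)
        out[v] = samp2(im, nx, ny, x + disp(v, 0), y + disp(v, 1));
  } else {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t v = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++v)
          out[v] = samp3(im, nx, ny, nz, x + disp(v, 0), y + disp(v, 1), z + disp(v, 2));
  }
  return out;
}

// Adjoint of ffd_eval_grid: scatter per-voxel vector values into the lattice.
// [[Rcpp::export]]
NumericVector ffd_scatter_cpp(NumericMatrix vals, double delta,
                              IntegerVector dims, IntegerVector cdim) {
  const int d = dims.size();
  size_t nc = 1; for (int k = 0; k < (int)cdim.size(); ++k) nc *= cdim[k];
  NumericVector grad(nc);
  grad.attr("dim") = cdim;
  if (d == 2) {
    const int nx = dims[0], ny = dims[1];
    const int ncx = cdim[0], ncy = cdim[1];
    const int Kx = ncx - 3, Ky = ncy - 3;
    std::vector<int> ixv(nx); std::vector<double> wxv(4 * nx);
    for (int x = 0; x < nx; ++x) { double t; span_of(x, delta, Kx, ixv[x], t); cubw(t, &wxv[4 * x]); }
    double wy[4];
    size_t v = 0;
    for (int y = 0; y < ny; ++y) {
      int iy; double ty; span_of(y, delta, Ky, iy, ty); cubw(ty, wy);
      for (int x = 0; x < nx; ++x, ++v) {
        const double* wx = &wxv[4 * x]; const int ix = ixv[x];
        for (int c = 0; c < 2; ++c) {
          double gv = vals(v, c);
          if (gv == 0.0) continue;
          double* cc = &grad[(size_t)c * ncx * ncy];
          for (int b = 0; b < 4; ++b) {
            double* col = cc + (size_t)(iy + b) * ncx + ix;
            double wyb = wy[b] * gv;
            col[0] += wx[0] * wyb; col[1] += wx[1] * wyb;
            col[2] += wx[2] * wyb; col[3] += wx[3] * wyb;
          }
        }
      }
    }
  } else {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
    const int Kx = ncx - 3, Ky = ncy - 3, Kz = ncz - 3;
    std::vector<int> ixv(nx), iyv(ny);
    std::vector<double> wxv(4 * nx), wyv(4 * ny);
    for (int x = 0; x < nx; ++x) { double t; span_of(x, delta, Kx, ixv[x], t); cubw(t, &wxv[4 * x]); }
    for (int y = 0; y < ny; ++y) { double t; span_of(y, delta, Ky, iyv[y], t); cubw(t, &wyv[4 * y]); }
    double wz[4];
    size_t v = 0;
    for (int z = 0; z < nz; ++z) {
      int iz; double tz; span_of(z, delta, Kz, iz, tz); cubw(tz, wz);
      for (int y = 0; y < ny; ++y) {
        const double* wy = &wyv[4 * y]; const int iy = iyv[y];
        for (int x = 0; x < nx; ++x, ++v) {
          const double* wx = &wxv[4 * x]; const int ix = ixv[x];
          for (int c = 0; c < 3; ++c) {
            double gv = vals(v, c);
            if (gv == 0.0) continue;
            double* cc = &grad[(size_t)c * ncx * ncy * ncz];
            for (int b3 = 0; b3 < 4; ++b3) {
              for (int b2 = 0; b2 < 4; ++b2) {
                double* col = cc + ((size_t)(iz + b3) * ncy + (iy + b2)) * ncx + ix;
                double wyz = wz[b3] * wy[b2] * gv;
                col[0] += wx[0] * wyz; col[1] += wx[1] * wyz;
                col[2] += wx[2] * wyz; col[3] += wx[3] * wyz;
              }
            }
          }
        }
      }
    }
  }
  return grad;
}

// Combined FFD registration objective:
//   E_sim = (1/N) sum (I - J(x+u))^2,  E_reg = 1/2 sum |forward-diff grad u|^2,
// with the gradient with respect to lattice coefficients.
// gradJ holds the d pre-computed central-difference gradient components of J.
// [[Rcpp::export]]
List ffd_objective_cpp(NumericVector I, NumericVector J, List gradJ,
                       IntegerVector dims, NumericVector coef, double delta,
                       double lambda, bool want_grad) {
  IntegerVector cdim = coef.attr("dim");
  const int d = dims.size();
  size_t nv = 1; for (int k = 0; k < d; ++k) nv *= dims[k];
  NumericMatrix u = ffd_eval_grid_cpp(coef, delta, dims);

  // similarity value and per-voxel similarity gradient (wrt u)
  double esim = 0.0;
  NumericMatrix dedu(nv, d);
  const double invN = 1.0 / (double)nv;
  if (d == 2) {
    const int nx = dims[0], ny = dims[1];
    const double* jm = &J[0];
    const double* gx = &as<NumericVector>(gradJ[0])[0];
    const double* gy = &as<NumericVector>(gradJ[1])[0];
    size_t v = 0;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++v) {
        double px = x + u(v, 0), py = y + u(v, 1);
        double jw = samp2(jm, nx, ny, px, py);
        double diff = jw - I[v];
        esim += diff * diff;
        if (want_grad) {
          double f = 2.0 * invN * diff;
          dedu(v, 0) = f * samp2(gx, nx, ny, px, py);
          dedu(v, 1) = f * samp2(gy, nx, ny, px, py);
        }
      }
  } else {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double* jm = &J[0];
    const double* gx = &as<NumericVector>(gradJ[0])[0];
    const double* gy = &as<NumericVector>(gradJ[1])[0];
    const double* gz = &as<NumericVector>(gradJ[2])[0];
    size_t v = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++v) {
          double px = x + u(v, 0), py = y + u(v, 1), pz = z + u(v, 2);
          double jw = samp3(jm, nx, ny, nz, px, py, pz);
          double diff = jw - I[v];
          esim += diff * diff;
          if (want_grad) {
            double f = 2.0 * invN * diff;
            dedu(v, 0) = f * samp3(gx, nx, ny, nz, px, py, pz);
            dedu(v, 1) = f * samp3(gy, nx, ny, nz, px, py, pz);
            dedu(v, 2) = f * samp3(gz, nx, ny, nz, px, py, pz);
          }
        }
  }
  esim *= invN;

  // regularization: squared norm of the forward-difference displacement
  // gradient, averaged over the voxel grid (voxel units), so E_sim and
  // E_reg share the per-voxel scale and lambda is dimensionless
  double ereg = 0.0;
  const double regw = invN;
  if (d == 2) {
    const int nx = dims[0], ny = dims[1];
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t v = (size_t)y * nx + x;
        for (int c = 0; c < 2; ++c) {
          if (x + 1 < nx) {
            double dif = u(v + 1, c) - u(v, c);
            ereg += 0.5 * dif * dif;
            if (want_grad && lambda != 0) { dedu(v + 1, c) += lambda * regw * dif; dedu(v, c) -= lambda * regw * dif; }
          }
          if (y + 1 < ny) {
            double dif = u(v + nx, c) - u(v, c);
            ereg += 0.5 * dif * dif;
            if (want_grad && lambda != 0) { dedu(v + nx, c) += lambda * regw * dif; dedu(v, c) -= lambda * regw * dif; }
          }
        }
      }
  } else {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const size_t sxy = (size_t)nx * ny;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t v = (size_t)z * sxy + (size_t)y * nx + x;
          for (int c = 0; c < 3; ++c) {
            if (x + 1 < nx) {
              double dif = u(v + 1, c) - u(v, c);
              ereg += 0.5 * dif * dif;
              if (want_grad && lambda != 0) { dedu(v + 1, c) += lambda * regw * dif; dedu(v, c) -= lambda * regw * dif; }
            }
            if (y + 1 < ny) {
              double dif = u(v + nx, c) - u(v, c);
              ereg += 0.5 * dif * dif;
              if (want_grad && lambda != 0) { dedu(v + nx, c) += lambda * regw * dif; dedu(v, c) -= lambda * regw * dif; }
            }
            if (z + 1 < nz) {
              double dif = u(v + sxy, c) - u(v, c);
              ereg += 0.5 * dif * dif;
              if (want_grad && lambda != 0) { dedu(v + sxy, c) += lambda * regw * dif; dedu(v, c) -= lambda * regw * dif; }
            }
          }
        }
  }

  ereg *= regw;
  List out = List::create(_["esim"] = esim, _["ereg"] = ereg,
                          _["eobj"] = esim + lambda * ereg);
  if (want_grad)
    out["grad"] = ffd_scatter_cpp(dedu, delta, dims, cdim);
  return out;
}
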