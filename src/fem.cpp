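// P1 simplex finite-element kernels: residual-based VMS assembly of the
// incompressible ALE Navier-Stokes equations, boundary (Neumann + backflow)
// terms, linear-elastostatic mesh-motion stiffness with Jacobian-based
// stiffening, point location with barycentric weights, and voxel connected
// components.
//
// Dof ordering is node-major: node k carries d velocity components followed
// by pressure, global dof = k*(d+1)+c.  Element connectivity arrives 0-based.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// invert small d x d matrix (column-major in Jm), returns det
static double inv_small(int d, const double* Jm, double* A) {
  if (d == 2) {
    double det = Jm[0] * Jm[3] - Jm[2] * Jm[1];
    double id = 1.0 / det;
    A[0] =  Jm[3] * id; A[2] = -Jm[2] * id;
    A[1] = -Jm[1] * id; A[3] =  Jm[0] * id;
    return det;
  }
  double a = Jm[0], b = Jm[3], c = Jm[6];
  double d1 = Jm[1], e = Jm[4], f = Jm[7];
  double g = Jm[2], h = Jm[5], i = Jm[8];
  double A11 = e * i - f * h, A12 = c * h - b * i, A13 = b * f - c * e;
  double A21 = f * g - d1 * i, A22 = a * i - c * g, A23 = c * d1 - a * f;
  double A31 = d1 * h - e * g, A32 = b * g - a * h, A33 = a * e - b * d1;
  double det = a * A11 + b * A21 + c * A31;
  double id = 1.0 / det;
  A[0] = A11 * id; A[3] = A12 * id; A[6] = A13 * id;
  A[1] = A21 * id; A[4] = A22 * id; A[7] = A23 * id;
  A[2] = A31 * id; A[5] = A32 * id; A[8] = A33 * id;
  return det;
}

// quadrature (degree-2 exact): barycentric coords + weights
static int quad_rule(int d, double bq[][4], double* wq) {
  if (d == 2) {
    double q[3][4] = {{0.5, 0.5, 0.0, 0}, {0.0, 0.5, 0.5, 0}, {0.5, 0.0, 0.5, 0}};
    for (int k = 0; k < 3; ++k) for (int j = 0; j < 4; ++j) bq[k][j] = q[k][j];
    wq[0] = wq[1] = wq[2] = 1.0 / 3.0;
    return 3;
  }
  const double aa = 0.585410196624969, bb = 0.138196601125011;
  for (int k = 0; k < 4; ++k) {
    for (int j = 0; j < 4; ++j) bq[k][j] = (j == k) ? aa : bb;
    wq[k] = 0.25;
  }
  return 4;
}

// [[Rcpp::export]]
List assemble_vms_cpp(NumericMatrix nodes, IntegerMatrix elems,
                      NumericMatrix v, NumericMatrix vdot, NumericVector p,
                      NumericMatrix vhat, double rho, double mu,
                      NumericVector fb, double dt, double Ct, double CI,
                      double cm, double cv, bool want_tangent) {
  const int d = nodes.ncol();
  const int nen = d + 1;
  const int nn = nodes.nrow();
  const int ne = elems.nrow();
  const int ndpn = d + 1;               // dofs per node
  const int ned = nen * ndpn;           // element dofs
  const double nu2 = (mu / rho) * (mu / rho);

  NumericVector R(nn * ndpn);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)ne * ned * ned);
    tj.reserve((size_t)ne * ned * ned);
    tx.reserve((size_t)ne * ned * ned);
  }

  double bq[4][4], wq[4];
  const int nq = quad_rule(d, bq, wq);

  double Ke[16 * 16];
  int badelem = 0;

  for (int e = 0; e < ne; ++e) {
    int en[4];
    double X[4][3], Jm[9], A[9], gradN[4][3], G[3][3], gv[3];
    for (int k = 0; k < nen; ++k) {
      en[k] = elems(e, k);
      for (int i = 0; i < d; ++i) X[k][i] = nodes(en[k], i);
    }
    for (int k = 0; k < d; ++k)
      for (int i = 0; i < d; ++i)
        Jm[k * d + i] = X[k + 1][i] - X[0][i];
    double det = inv_small(d, Jm, A);
    double vol = det / (d == 2 ? 2.0 : 6.0);
    if (!(vol > 0.0)) { ++badelem; continue; }
    for (int k = 1; k <= d; ++k)
      for (int i = 0; i < d; ++i) gradN[k][i] = A[(k - 1) + d * i];
    for (int i = 0; i < d; ++i) {
      gradN[0][i] = 0.0;
      for (int k = 1; k <= d; ++k) gradN[0][i] -= gradN[k][i];
    }
    for (int i = 0; i < d; ++i) {
      gv[i] = 0.0;
      for (int k = 0; k < d; ++k) gv[i] += A[k + d * i];
      for (int j = 0; j < d; ++j) {
        G[i][j] = 0.0;
        for (int k = 0; k < d; ++k) G[i][j] += A[k + d * i] * A[k + d * j];
      }
    }
    double gg = 0.0, GG = 0.0;
    for (int i = 0; i < d; ++i) {
      gg += gv[i] * gv[i];
      for (int j = 0; j < d; ++j) GG += G[i][j] * G[i][j];
    }
    // element-constant velocity gradient, divergence, pressure gradient
    double gradv[3][3], divv = 0.0, gradp[3];
    for (int i = 0; i < d; ++i) {
      gradp[i] = 0.0;
      for (int k = 0; k < nen; ++k) gradp[i] += p[en[k]] * gradN[k][i];
      for (int j = 0; j < d; ++j) {
        gradv[i][j] = 0.0;
        for (int k = 0; k < nen; ++k) gradv[i][j] += v(en[k], i) * gradN[k][j];
      }
      divv += gradv[i][i];
    }
    if (want_tangent) std::fill(Ke, Ke + ned * ned, 0.0);

    for (int q = 0; q < nq; ++q) {
      double N[4];
      for (int k = 0; k < nen; ++k) N[k] = bq[q][k];
      double vq[3], vdq[3], vhq[3], aq[3], pq = 0.0;
      for (int i = 0; i < d; ++i) { vq[i] = vdq[i] = vhq[i] = 0.0; }
      for (int k = 0; k < nen; ++k) {
        pq += N[k] * p[en[k]];
        for (int i = 0; i < d; ++i) {
          vq[i] += N[k] * v(en[k], i);
          vdq[i] += N[k] * vdot(en[k], i);
          vhq[i] += N[k] * vhat(en[k], i);
        }
      }
      for (int i = 0; i < d; ++i) aq[i] = vq[i] - vhq[i];
      double aGa = 0.0;
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j) aGa += aq[i] * G[i][j] * aq[j];
      double tauM = 1.0 / std::sqrt(Ct / (dt * dt) + aGa + CI * nu2 * GG);
      double tauC = 1.0 / (tauM * gg);
      // momentum residual (P1: viscous Laplacian vanishes element-wise)
      double rM[3], advv[3];
      for (int i = 0; i < d; ++i) {
        advv[i] = 0.0;
        for (int j = 0; j < d; ++j) advv[i] += gradv[i][j] * aq[j];
        rM[i] = rho * (vdq[i] + advv[i] - fb[i]) + gradp[i];
      }
      double tmr[3];
      for (int i = 0; i < d; ++i) tmr[i] = tauM * rM[i];
      double tGt = 0.0;
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j) tGt += tmr[i] * G[i][j] * tmr[j];
      double tauB = (tGt > 1e-24) ? 1.0 / std::sqrt(tGt) : 0.0;

      double w = wq[q] * vol;
      double adgN[4], tdgN[4];   // (a . gradN_a), (tmr . gradN_a)
      for (int k = 0; k < nen; ++k) {
        adgN[k] = tdgN[k] = 0.0;
        for (int i = 0; i < d; ++i) {
          adgN[k] += aq[i] * gradN[k][i];
          tdgN[k] += tmr[i] * gradN[k][i];
        }
      }
      double gvt[3];              // (tmr . grad) v  (component i)
      for (int i = 0; i < d; ++i) {
        gvt[i] = 0.0;
        for (int j = 0; j < d; ++j) gvt[i] += gradv[i][j] * tmr[j];
      }

      for (int a = 0; a < nen; ++a) {
        const int rowbase = en[a] * ndpn;
        for (int i = 0; i < d; ++i) {
          double r = N[a] * rho * (vdq[i] + advv[i] - fb[i])
                   - gradN[a][i] * pq
                   + rho * tauC * divv * gradN[a][i]
                   + adgN[a] * tmr[i]
                   - N[a] * gvt[i]
                   - (1.0 / rho) * tmr[i] * tdgN[a]
                   + tauB * tdgN[a] * gvt[i];
          double visc = 0.0;
          for (int j = 0; j < d; ++j)
            visc += (gradv[i][j] + gradv[j][i]) * gradN[a][j];
          r += mu * visc;
          R[rowbase + i] += w * r;
        }
        double rp = N[a] * divv + (1.0 / rho) * tdgN[a];
        R[rowbase + d] += w * rp;
      }

      if (want_tangent) {
        for (int b = 0; b < nen; ++b) {
          double gNb[3];
          for (int i = 0; i < d; ++i) gNb[i] = gradN[b][i];
          double adgNb = adgN[b], tdgNb = tdgN[b];
          double gNagNb[4];
          for (int a = 0; a < nen; ++a) {
            gNagNb[a] = 0.0;
            for (int i = 0; i < d; ++i) gNagNb[a] += gradN[a][i] * gNb[i];
          }
          for (int j = 0; j < d; ++j) {
            // dr for velocity unknown (b, j): dr[i] = diagc*delta_ij + offc[i]
            double diagc = rho * (cm * N[b] + cv * adgNb);
            double offc[3];
            for (int i = 0; i < d; ++i) offc[i] = rho * cv * N[b] * gradv[i][j];
            for (int a = 0; a < nen; ++a) {
              double drdga = 0.0;  // dr . gradN_a
              for (int k = 0; k < d; ++k) drdga += offc[k] * gradN[a][k];
              drdga += diagc * gradN[a][j];
              for (int i = 0; i < d; ++i) {
                double dr_i = offc[i] + (i == j ? diagc : 0.0);
                double kk =
                    N[a] * dr_i
                  + cv * mu * ((i == j ? gNagNb[a] : 0.0) + gNb[i] * gradN[a][j])
                  + adgN[a] * tauM * dr_i + cv * N[b] * gradN[a][j] * tmr[i];
                // term6: -N_a tauM (dr . grad)v - cv N_a (tmr . gradN_b) dv
                double t6 = 0.0;
                for (int k = 0; k < d; ++k)
                  t6 += gradv[i][k] * (offc[k] + (k == j ? diagc : 0.0));
                kk -= N[a] * tauM * t6
                    + cv * N[a] * tdgNb * (i == j ? 1.0 : 0.0);
                kk -= (tauM / rho) * (dr_i * tdgN[a] + tmr[i] * drdga);
                kk += rho * tauC * cv * gradN[a][i] * gNb[j];
                kk += tauB * cv * tdgN[a] * tdgNb * (i == j ? 1.0 : 0.0);
                Ke[(a * ndpn + i) * ned + (b * ndpn + j)] += w * kk;
              }
              // pressure test row vs velocity unknown
              double kpv = cv * N[a] * gNb[j] + (tauM / rho) * drdga;
              Ke[(a * ndpn + d) * ned + (b * ndpn + j)] += w * kpv;
            }
          }
          // pressure unknown (b): dr[i] = gNb[i]
          for (int a = 0; a < nen; ++a) {
            double drdga = gNagNb[a];
            for (int i = 0; i < d; ++i) {
              double kk = -gradN[a][i] * N[b]
                        + adgN[a] * tauM * gNb[i];
              double t6 = 0.0;
              for (int k = 0; k < d; ++k) t6 += gradv[i][k] * gNb[k];
              kk -= N[a] * tauM * t6;
              kk -= (tauM / rho) * (gNb[i] * tdgN[a] + tmr[i] * drdga);
              Ke[(a * ndpn + i) * ned + (b * ndpn + d)] += w * kk;
            }
            Ke[(a * ndpn + d) * ned + (b * ndpn + d)] += w * (tauM / rho) * drdga;
          }
        }
      }
    }

    if (want_tangent) {
      for (int a = 0; a < nen; ++a)
        for (int ia = 0; ia < ndpn; ++ia)
          for (int b = 0; b < nen; ++b)
            for (int jb = 0; jb < ndpn; ++jb) {
              double val = Ke[(a * ndpn + ia) * ned + (b * ndpn + jb)];
              if (val != 0.0) {
                ti.push_back(en[a] * ndpn + ia + 1);
                tj.push_back(en[b] * ndpn + jb + 1);
                tx.push_back(val);
              }
            }
    }
  }

  List out = List::create(_["residual"] = R, _["n_bad_elements"] = badelem);
  if (want_tangent) {
    out["i"] = IntegerVector(ti.begin(), ti.end());
    out["j"] = IntegerVector(tj.begin(), tj.end());
    out["x"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// Neumann traction + backflow stabilization on boundary faces.
// faces: nf x d (0-based node ids), ordered so the outward normal is
// n = rot90(t) in 2-D (CCW boundary) and cross(v1-v0, v2-v0) in 3-D.
// traction: nf x d prescribed traction h (usually zero).
// Adds  -(w, h) - (w, rho*beta*(v.n)_- v)  to the residual R = B - F.
// [[Rcpp::export]]
List assemble_boundary_cpp(NumericMatrix nodes, IntegerMatrix faces,
                           NumericMatrix traction, NumericMatrix v,
                           double rho, double beta, double cv,
                           bool want_tangent) {
  const int d = nodes.ncol();
  const int nfn = d;                 // nodes per face
  const int nf = faces.nrow();
  const int nn = nodes.nrow();
  const int ndpn = d + 1;
  NumericVector R(nn * ndpn);
  std::vector<int> ti, tj;
  std::vector<double> tx;

  // face quadrature: 2-pt Gauss on edges, midedge 3-pt on triangles
  double fq[3][3]; double fw[3]; int nq;
  if (d == 2) {
    const double g = 0.5 / std::sqrt(3.0);
    fq[0][0] = 0.5 + g; fq[0][1] = 0.5 - g;
    fq[1][0] = 0.5 - g; fq[1][1] = 0.5 + g;
    fw[0] = fw[1] = 0.5; nq = 2;
  } else {
    double q[3][3] = {{0.5, 0.5, 0.0}, {0.0, 0.5, 0.5}, {0.5, 0.0, 0.5}};
    for (int k = 0; k < 3; ++k) for (int j = 0; j < 3; ++j) fq[k][j] = q[k][j];
    fw[0] = fw[1] = fw[2] = 1.0 / 3.0; nq = 3;
  }

  for (int f = 0; f < nf; ++f) {
    int fn[3];
    double X[3][3];
    for (int k = 0; k < nfn; ++k) {
      fn[k] = faces(f, k);
      for (int i = 0; i < d; ++i) X[k][i] = nodes(fn[k], i);
    }
    double nrm[3], area;
    if (d == 2) {
      double tx0 = X[1][0] - X[0][0], ty0 = X[1][1] - X[0][1];
      area = std::sqrt(tx0 * tx0 + ty0 * ty0);
      nrm[0] = ty0 / area; nrm[1] = -tx0 / area;
    } else {
      double u[3], w2[3];
      for (int i = 0; i < 3; ++i) { u[i] = X[1][i] - X[0][i]; w2[i] = X[2][i] - X[0][i]; }
      nrm[0] = u[1] * w2[2] - u[2] * w2[1];
      nrm[1] = u[2] * w2[0] - u[0] * w2[2];
      nrm[2] = u[0] * w2[1] - u[1] * w2[0];
      double l = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
      area = 0.5 * l;
      for (int i = 0; i < 3; ++i) nrm[i] /= l;
    }
    for (int q = 0; q < nq; ++q) {
      double vq[3] = {0, 0, 0};
      for (int k = 0; k < nfn; ++k)
        for (int i = 0; i < d; ++i) vq[i] += fq[q][k] * v(fn[k], i);
      double vn = 0.0;
      for (int i = 0; i < d; ++i) vn += vq[i] * nrm[i];
      double vneg = vn < 0.0 ? vn : 0.0;
      double w = fw[q] * area;
      for (int a = 0; a < nfn; ++a) {
        for (int i = 0; i < d; ++i) {
          double r = -fq[q][a] * traction(f, i)
                     - rho * beta * vneg * fq[q][a] * vq[i];
          R[fn[a] * ndpn + i] += w * r;
        }
      }
      if (want_tangent && vneg < 0.0) {
        for (int a = 0; a < nfn; ++a)
          for (int b = 0; b < nfn; ++b)
            for (int i = 0; i < d; ++i) {
              double kk = -rho * beta * vneg * cv * fq[q][a] * fq[q][b];
              ti.push_back(fn[a] * ndpn + i + 1);
              tj.push_back(fn[b] * ndpn + i + 1);
              tx.push_back(w * kk);
            }
      }
    }
  }
  List out = List::create(_["residual"] = R);
  if (want_tangent) {
    out["i"] = IntegerVector(ti.begin(), ti.end());
    out["j"] = IntegerVector(tj.begin(), tj.end());
    out["x"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// Linear elastostatic stiffness with Jacobian-based stiffening:
// each element stiffness is scaled by (vbar / V_e)^chi.
// Dofs: d per node, node-major.
// [[Rcpp::export]]
List assemble_elasticity_cpp(NumericMatrix nodes, IntegerMatrix elems,
                             double chi, double nu) {
  const int d = nodes.ncol();
  const int nen = d + 1;
  const int ne = elems.nrow();
  const double E = 1.0;
  const double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  const double mu = E / (2 * (1 + nu));

  std::vector<double> vols(ne);
  double vbar = 0.0;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * nen * nen * d * d);
  tj.reserve((size_t)ne * nen * nen * d * d);
  tx.reserve((size_t)ne * nen * nen * d * d);

  // first pass: volumes
  for (int e = 0; e < ne; ++e) {
    double X[4][3], Jm[9], A[9];
    for (int k = 0; k < nen; ++k)
      for (int i = 0; i < d; ++i) X[k][i] = nodes(elems(e, k), i);
    for (int k = 0; k < d; ++k)
      for (int i = 0; i < d; ++i) Jm[k * d + i] = X[k + 1][i] - X[0][i];
    double det = inv_small(d, Jm, A);
    vols[e] = det / (d == 2 ? 2.0 : 6.0);
    vbar += std::fabs(vols[e]);
  }
  vbar /= ne;

  for (int e = 0; e < ne; ++e) {
    int en[4];
    double X[4][3], Jm[9], A[9], gradN[4][3];
    for (int k = 0; k < nen; ++k) {
      en[k] = elems(e, k);
      for (int i = 0; i < d; ++i) X[k][i] = nodes(en[k], i);
    }
    for (int k = 0; k < d; ++k)
      for (int i = 0; i < d; ++i) Jm[k * d + i] = X[k + 1][i] - X[0][i];
    inv_small(d, Jm, A);
    double vol = vols[e];
    if (vol <= 0) continue;
    for (int k = 1; k <= d; ++k)
      for (int i = 0; i < d; ++i) gradN[k][i] = A[(k - 1) + d * i];
    for (int i = 0; i < d; ++i) {
      gradN[0][i] = 0.0;
      for (int k = 1; k <= d; ++k) gradN[0][i] -= gradN[k][i];
    }
    double stiff = std::pow(vbar / vol, chi);
    for (int a = 0; a < nen; ++a)
      for (int b = 0; b < nen; ++b) {
        double gab = 0.0;
        for (int i = 0; i < d; ++i) gab += gradN[a][i] * gradN[b][i];
        for (int i = 0; i < d; ++i)
          for (int j = 0; j < d; ++j) {
            double kk = mu * ((i == j ? gab : 0.0) + gradN[b][i] * gradN[a][j])
                      + lam * gradN[a][i] * gradN[b][j];
            ti.push_back(en[a] * d + i + 1);
            tj.push_back(en[b] * d + j + 1);
            tx.push_back(vol * stiff * kk);
          }
      }
  }
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()));
}

// Locate query points in a simplex mesh; returns 1-based element id,
// barycentric weights, and whether the point was strictly located (points
// not inside any element fall back to the element with largest minimum
// barycentric coordinate).
// [[Rcpp::export]]
List locate_points_cpp(NumericMatrix nodes, IntegerMatrix elems, NumericMatrix pts) {
  const int d = nodes.ncol();
  const int nen = d + 1;
  const int ne = elems.nrow();
  const int np = pts.nrow();
  // precompute inverse maps and bboxes
  std::vector<double> Ainv((size_t)ne * d * d), X0((size_t)ne * d);
  std::vector<double> blo((size_t)ne * d), bhi((size_t)ne * d);
  for (int e = 0; e < ne; ++e) {
    double X[4][3], Jm[9], A[9];
    for (int k = 0; k < nen; ++k)
      for (int i = 0; i < d; ++i) X[k][i] = nodes(elems(e, k), i);
    for (int k = 0; k < d; ++k)
      for (int i = 0; i < d; ++i) Jm[k * d + i] = X[k + 1][i] - X[0][i];
    inv_small(d, Jm, A);
    for (int i = 0; i < d * d; ++i) Ainv[(size_t)e * d * d + i] = A[i];
    for (int i = 0; i < d; ++i) {
      X0[(size_t)e * d + i] = X[0][i];
      double lo = X[0][i], hi = X[0][i];
      for (int k = 1; k < nen; ++k) {
        if (X[k][i] < lo) lo = X[k][i];
        if (X[k][i] > hi) hi = X[k][i];
      }
      blo[(size_t)e * d + i] = lo - 1e-12;
      bhi[(size_t)e * d + i] = hi + 1e-12;
    }
  }
  IntegerVector elem(np);
  NumericMatrix bary(np, nen);
  LogicalVector inside(np);
  const double tol = 1e-9;
  // margin for the bbox prefilter, relative to the mesh extent
  double span = 0.0;
  for (int i = 0; i < d; ++i) {
    double lo = 1e300, hi = -1e300;
    for (int e = 0; e < ne; ++e) {
      if (blo[(size_t)e * d + i] < lo) lo = blo[(size_t)e * d + i];
      if (bhi[(size_t)e * d + i] > hi) hi = bhi[(size_t)e * d + i];
    }
    if (hi - lo > span) span = hi - lo;
  }
  const double margin = 1e-6 * span;
  for (int q = 0; q < np; ++q) {
    int beste = -1; double bestb[4] = {0, 0, 0, 0};
    bool found = false;
    for (int e = 0; e < ne && !found; ++e) {
      bool out = false;
      for (int i = 0; i < d; ++i) {
        double x = pts(q, i);
        if (x < blo[(size_t)e * d + i] - margin ||
            x > bhi[(size_t)e * d + i] + margin) { out = true; break; }
      }
      if (out) continue;
      double bc[4]; bc[0] = 1.0;
      const double* A = &Ainv[(size_t)e * d * d];
      for (int k = 0; k < d; ++k) {
        double s = 0.0;
        for (int i = 0; i < d; ++i)
          s += A[k + d * i] * (pts(q, i) - X0[(size_t)e * d + i]);
        bc[k + 1] = s; bc[0] -= s;
      }
      double minb = bc[0];
      for (int k = 1; k < nen; ++k) if (bc[k] < minb) minb = bc[k];
      if (minb >= -tol) {
        found = true; beste = e;
        for (int k = 0; k < nen; ++k) bestb[k] = bc[k];
      }
    }
    if (!found) {
      // nearest-element projection: clamp the barycentric weights of every
      // element, renormalize, and keep the closest resulting point
      double bestdist = 1e300;
      for (int e = 0; e < ne; ++e) {
        double bc[4]; bc[0] = 1.0;
        const double* A = &Ainv[(size_t)e * d * d];
        for (int k = 0; k < d; ++k) {
          double s = 0.0;
          for (int i = 0; i < d; ++i)
            s += A[k + d * i] * (pts(q, i) - X0[(size_t)e * d + i]);
          bc[k + 1] = s; bc[0] -= s;
        }
        double cb[4], ssum = 0.0;
        for (int k = 0; k < nen; ++k) { cb[k] = bc[k] < 0.0 ? 0.0 : bc[k]; ssum += cb[k]; }
        if (ssum <= 0) continue;
        for (int k = 0; k < nen; ++k) cb[k] /= ssum;
        double dist2 = 0.0;
        for (int i = 0; i < d; ++i) {
          double xi = 0.0;
          for (int k = 0; k < nen; ++k) xi += cb[k] * nodes(elems(e, k), i);
          double df = xi - pts(q, i);
          dist2 += df * df;
        }
        if (dist2 < bestdist) {
          bestdist = dist2; beste = e;
          for (int k = 0; k < nen; ++k) bestb[k] = cb[k];
        }
      }
    }
    elem[q] = beste + 1;
    inside[q] = found;
    double s = 0.0;
    for (int k = 0; k < nen; ++k) {
      double b = bestb[k] < 0.0 ? 0.0 : bestb[k];
      bary(q, k) = b; s += b;
    }
    for (int k = 0; k < nen; ++k) bary(q, k) /= (s > 0 ? s : 1.0);
  }
  return List::create(_["elem"] = elem, _["bary"] = bary, _["inside"] = inside);
}

// Connected components of a voxel mask (face connectivity). 0 = background.
// [[Rcpp::export]]
IntegerVector conncomp_cpp(LogicalVector mask, IntegerVector dims) {
  const int d = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (d == 3) ? dims[2] : 1;
  const size_t nv = (size_t)nx * ny * nz;
  IntegerVector lab(nv);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < nv; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear(); stack.push_back(s); lab[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      int nnb = (d == 3) ? 6 : 4;
      for (int k = 0; k < nnb; ++k) {
        int xx = x + nb[k][0], yy = y + nb[k][1], zz = z + nb[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        size_t w = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}
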