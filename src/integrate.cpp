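#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Explicit forward-Euler integration of the coupled tumor/vasculature
// cross-diffusion system over a chunk of steps with frozen diffusion,
// distance and effective-rate fields. The carrying capacity responds to the
// current blood volume fraction at every step. Fluxes are face-centred
// (harmonic-mean D, arithmetic-mean fractions) with zero flux through mask
// boundaries, so total burden is conserved exactly when growth and death
// vanish.

// [[Rcpp::export]]
List integrate_chunk_cpp(NumericVector phi_T_in, NumericVector phi_V_in,
                         LogicalVector mask,
                         NumericVector D_T, NumericVector D_V,
                         NumericVector kp_T, NumericVector kd_T,
                         NumericVector kp_V, NumericVector kd_V,
                         NumericVector kd_V_rt, NumericVector dfield,
                         double theta_min, double theta_max, double theta_V,
                         double phi_V_thresh,
                         IntegerVector dims, NumericVector h,
                         double dt, int nsteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector phi_T = clone(phi_T_in);
  NumericVector phi_V = clone(phi_V_in);

  // face lists per axis: pairs (p, q = p + stride) with both voxels in mask
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  std::vector<int> fp[3], fq[3];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
        if (!mask[p]) continue;
        if (i + 1 < nx && mask[p + stride[0]]) { fp[0].push_back(p); fq[0].push_back(p + stride[0]); }
        if (j + 1 < ny && mask[p + stride[1]]) { fp[1].push_back(p); fq[1].push_back(p + stride[1]); }
        if (k + 1 < nz && mask[p + stride[2]]) { fp[2].push_back(p); fq[2].push_back(p + stride[2]); }
      }
  std::vector<R_xlen_t> mvox;
  for (R_xlen_t p = 0; p < n; ++p) if (mask[p]) mvox.push_back(p);

  std::vector<double> a(n, 0.0), b(n, 0.0), thT(n, 0.0), rT(n, 0.0), rV(n, 0.0);
  const double slope = (theta_max - theta_min) / phi_V_thresh;
  double min_seen = 0.0, max_seen = 1.0;
  bool bad = false;

  for (int step = 0; step < nsteps && !bad; ++step) {
    for (size_t m = 0; m < mvox.size(); ++m) {
      R_xlen_t p = mvox[m];
      double pv = phi_V[p];
      double th = (pv >= phi_V_thresh) ? theta_max : theta_min + pv * slope;
      thT[p] = th;
      double tv = th + theta_V;
      a[p] = phi_T[p] / tv;
      b[p] = pv / tv;
      rT[p] = 0.0;
      rV[p] = 0.0;
    }
    for (int ax = 0; ax < 3; ++ax) {
      const double ih = 1.0 / h[ax];
      const double ih2 = ih * ih;
      const size_t nf = fp[ax].size();
      const int *P = fp[ax].data();
      const int *Q = fq[ax].data();
      for (size_t f = 0; f < nf; ++f) {
        const R_xlen_t p = P[f], q = Q[f];
        const double da = a[q] - a[p];
        const double db = b[q] - b[p];
        const double af = 0.5 * (a[p] + a[q]);
        const double bf = 0.5 * (b[p] + b[q]);
        double sT = D_T[p] + D_T[q];
        double DTf = (sT > 0.0) ? 2.0 * D_T[p] * D_T[q] / sT : 0.0;
        double sV = D_V[p] + D_V[q];
        double DVf = (sV > 0.0) ? 2.0 * D_V[p] * D_V[q] / sV : 0.0;
        const double FT = DTf * ((1.0 - bf) * da + af * db) * ih2;
        const double FV = DVf * ((1.0 - af) * db + bf * da) * ih2;
        rT[p] += FT; rT[q] -= FT;
        rV[p] += FV; rV[q] -= FV;
      }
    }
    for (size_t m = 0; m < mvox.size(); ++m) {
      R_xlen_t p = mvox[m];
      const double pt = phi_T[p], pv = phi_V[p];
      rT[p] += kp_T[p] * pt * (1.0 - pt / thT[p]) - kd_T[p] * pt;
      rV[p] += kp_V[p] * pv * (1.0 - pv / theta_V) * dfield[p]
             - kd_V[p] * pv * (1.0 - dfield[p]) - kd_V_rt[p] * pv;
      double nt = pt + dt * rT[p];
      double nv = pv + dt * rV[p];
      if (!R_finite(nt) || !R_finite(nv)) { bad = true; break; }
      if (nt < min_seen) min_seen = nt;
      if (nv < min_seen) min_seen = nv;
      if (nt > max_seen) max_seen = nt;
      if (nv > max_seen) max_seen = nv;
      phi_T[p] = nt < 0.0 ? 0.0 : (nt > 1.0 ? 1.0 : nt);
      phi_V[p] = nv < 0.0 ? 0.0 : (nv > 1.0 ? 1.0 : nv);
    }
  }

  return List::create(_["phi_T"] = phi_T, _["phi_V"] = phi_V,
                      _["min_value"] = min_seen, _["max_value"] = max_seen,
                      _["failed"] = bad);
}

// Minimum anisotropic Euclidean distance from each tumor voxel to the tumor
// boundary (tumor voxels with a face neighbour outside the mask or the
// domain). Returns -1 outside the tumor mask, and the boundary-set distance
// (0 on boundary voxels) inside.
// [[Rcpp::export]]
NumericVector boundary_distance_cpp(LogicalVector tumor, IntegerVector dims,
                                    NumericVector h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> bx, by, bz;
  std::vector<R_xlen_t> tvox;
  std::vector<double> tx, ty, tz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
        if (!tumor[p]) continue;
        bool bd = (i == 0 || !tumor[p - 1]) || (i == nx - 1 || !tumor[p + 1]) ||
                  (j == 0 || !tumor[p - nx]) || (j == ny - 1 || !tumor[p + nx]) ||
                  (k == 0 || !tumor[p - (R_xlen_t)nx * ny]) ||
                  (k == nz - 1 || !tumor[p + (R_xlen_t)nx * ny]);
        tvox.push_back(p);
        tx.push_back((i + 1) * h[0]); ty.push_back((j + 1) * h[1]); tz.push_back((k + 1) * h[2]);
        if (bd) { bx.push_back((i + 1) * h[0]); by.push_back((j + 1) * h[1]); bz.push_back((k + 1) * h[2]); }
      }
  NumericVector out(n, -1.0);
  for (size_t t = 0; t < tvox.size(); ++t) {
    double best = R_PosInf;
    for (size_t b = 0; b < bx.size(); ++b) {
      double dx = tx[t] - bx[b], dy = ty[t] - by[b], dz = tz[t] - bz[b];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[tvox[t]] = std::sqrt(best);
  }
  return out;
}
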