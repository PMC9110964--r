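#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based index (x, y, z);
// returns defval outside the grid support.
static inline double trilerp(const double* v, const int* d,
                             double x, double y, double z, double defval) {
  if (x < 0 || y < 0 || z < 0 ||
      x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1) return defval;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == d[0] - 1) x0--; if (y0 == d[1] - 1) y0--; if (z0 == d[2] - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const long nx = d[0], nxy = (long)d[0] * d[1];
  const double* p = v + x0 + nx * y0 + nxy * z0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[nxy] * (1 - fx) + p[nxy + 1] * fx;
  double c11 = p[nxy + nx] * (1 - fx) + p[nxy + nx + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample `mov` onto the reference grid through a rigid map
// q = rot (p - center) + center + trans applied to reference-space
// physical points p.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector mov, IntegerVector mdim,
                                 NumericVector mspc, NumericVector morg,
                                 NumericMatrix mdirinv,
                                 IntegerVector rdim, NumericVector rspc,
                                 NumericVector rorg, NumericMatrix rdir,
                                 NumericMatrix rot, NumericVector trans,
                                 NumericVector center, double defval) {
  const int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  int md[3] = {mdim[0], mdim[1], mdim[2]};
  NumericVector out((long)nx * ny * nz);
  const double* mv = mov.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double ix = i * rspc[0], iy = j * rspc[1], iz = k * rspc[2];
        double px = rorg[0] + rdir(0,0)*ix + rdir(0,1)*iy + rdir(0,2)*iz;
        double py = rorg[1] + rdir(1,0)*ix + rdir(1,1)*iy + rdir(1,2)*iz;
        double pz = rorg[2] + rdir(2,0)*ix + rdir(2,1)*iy + rdir(2,2)*iz;
        double cx = px - center[0], cy = py - center[1], cz = pz - center[2];
        double qx = rot(0,0)*cx + rot(0,1)*cy + rot(0,2)*cz + center[0] + trans[0];
        double qy = rot(1,0)*cx + rot(1,1)*cy + rot(1,2)*cz + center[1] + trans[1];
        double qz = rot(2,0)*cx + rot(2,1)*cy + rot(2,2)*cz + center[2] + trans[2];
        double ox = qx - morg[0], oy = qy - morg[1], oz = qz - morg[2];
        double mx = (mdirinv(0,0)*ox + mdirinv(0,1)*oy + mdirinv(0,2)*oz) / mspc[0];
        double my = (mdirinv(1,0)*ox + mdirinv(1,1)*oy + mdirinv(1,2)*oz) / mspc[1];
        double mz = (mdirinv(2,0)*ox + mdirinv(2,1)*oy + mdirinv(2,2)*oz) / mspc[2];
        out[i + (long)nx * (j + (long)ny * k)] =
          trilerp(mv, md, mx, my, mz, defval);
      }
  out.attr("dim") = rdim;
  return out;
}

// Negated mutual information between fixed-volume samples and the moving
// volume evaluated through the rigid map, from a joint histogram with
// linear (partial-volume) binning in both intensity axes. Samples mapping
// outside the moving grid are dropped; if fewer than 10% survive the
// metric is returned as the worst value (0 = no shared information).
// [[Rcpp::export]]
double cpp_mi_neg(NumericVector fvals, NumericMatrix fpts,
                  NumericVector mov, IntegerVector mdim,
                  NumericVector mspc, NumericVector morg,
                  NumericMatrix mdirinv,
                  NumericMatrix rot, NumericVector trans,
                  NumericVector center, int nbins,
                  double fmin, double fmax, double mmin, double mmax) {
  int md[3] = {mdim[0], mdim[1], mdim[2]};
  const double* mv = mov.begin();
  const int n = fvals.size();
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  const double fsc = (nbins - 1) / std::max(fmax - fmin, 1e-12);
  const double msc = (nbins - 1) / std::max(mmax - mmin, 1e-12);
  long valid = 0;
  for (int s = 0; s < n; ++s) {
    double cx = fpts(s,0) - center[0], cy = fpts(s,1) - center[1],
           cz = fpts(s,2) - center[2];
    double qx = rot(0,0)*cx + rot(0,1)*cy + rot(0,2)*cz + center[0] + trans[0];
    double qy = rot(1,0)*cx + rot(1,1)*cy + rot(1,2)*cz + center[1] + trans[1];
    double qz = rot(2,0)*cx + rot(2,1)*cy + rot(2,2)*cz + center[2] + trans[2];
    double ox = qx - morg[0], oy = qy - morg[1], oz = qz - morg[2];
    double mx = (mdirinv(0,0)*ox + mdirinv(0,1)*oy + mdirinv(0,2)*oz) / mspc[0];
    double my = (mdirinv(1,0)*ox + mdirinv(1,1)*oy + mdirinv(1,2)*oz) / mspc[1];
    double mz = (mdirinv(2,0)*ox + mdirinv(2,1)*oy + mdirinv(2,2)*oz) / mspc[2];
    if (mx < 0 || my < 0 || mz < 0 ||
        mx > md[0]-1 || my > md[1]-1 || mz > md[2]-1) continue;
    double m = trilerp(mv, md, mx, my, mz, 0.0);
    double bf = (fvals[s] - fmin) * fsc;
    double bm = (m - mmin) * msc;
    bf = std::min(std::max(bf, 0.0), (double)nbins - 1);
    bm = std::min(std::max(bm, 0.0), (double)nbins - 1);
    int f0 = std::min((int)bf, nbins - 2), m0 = std::min((int)bm, nbins - 2);
    double wf = bf - f0, wm = bm - m0;
    joint[f0 * nbins + m0]         += (1 - wf) * (1 - wm);
    joint[(f0 + 1) * nbins + m0]   += wf * (1 - wm);
    joint[f0 * nbins + m0 + 1]     += (1 - wf) * wm;
    joint[(f0 + 1) * nbins + m0 + 1] += wf * wm;
    ++valid;
  }
  if (valid < std::max(100L, (long)(0.1 * n))) return 0.0;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double p = joint[a * nbins + b] / valid;
      joint[a * nbins + b] = p;
      pf[a] += p; pm[b] += p;
    }
  double mi = 0.0;
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double p = joint[a * nbins + b];
      if (p > 1e-12 && pf[a] > 1e-12 && pm[b] > 1e-12)
        mi += p * std::log(p / (pf[a] * pm[b]));
    }
  return -mi;
}

// Trilinear interpolation of a volume at continuous 0-based index points;
// used to take metric samples off-grid (jittered), which suppresses the
// grid-alignment interpolation artifact of mutual information.
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts, double defval) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const double* v = vol.begin();
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = trilerp(v, d, pts(i,0), pts(i,1), pts(i,2), defval);
  return out;
}
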