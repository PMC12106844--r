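// Overdamped contact mechanics for rod-shaped cells confined to the x-z plane.
//
// Cells are spherocylinders: a segment of length `len` (pole to pole, caps
// excluded) with radius r0. Forces: Hertz-like repulsion at the closest points
// of two rod segments, Hertz-like repulsion of penetrating points against the
// agar half-space z < 0, a surface-tension spring pulling cell tops that
// protrude above the smoothed colony outline back down, and a small settling
// force. Motion is overdamped: velocity = force / (drag * total length),
// angular velocity = torque / (drag * L^3 / 12).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

// Closest points between segments p1+s*d1 (s in [0,1]) and p2+t*d2.
static void seg_seg_closest(double p1x, double p1z, double d1x, double d1z,
                            double p2x, double p2z, double d2x, double d2z,
                            double &s, double &t) {
  const double a = d1x * d1x + d1z * d1z;
  const double e = d2x * d2x + d2z * d2z;
  const double rx = p1x - p2x, rz = p1z - p2z;
  const double f = d2x * rx + d2z * rz;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; return; }
  if (a <= EPS) { s = 0.0; t = clamp01(f / e); return; }
  const double c = d1x * rx + d1z * rz;
  if (e <= EPS) { t = 0.0; s = clamp01(-c / a); return; }
  const double b = d1x * d2x + d1z * d2z;
  const double denom = a * e - b * b;
  s = (denom > EPS) ? clamp01((b * f - c * e) / denom) : 0.0;
  t = (b * s + f) / e;
  if (t < 0.0)      { t = 0.0; s = clamp01(-c / a); }
  else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
}

struct Forces {
  std::vector<double> fx_cc, fz_cc, tq_cc, fx_ext, fz_ext, tq_ext;
  double max_overlap;   // deepest cell-cell overlap seen, for dt control
  double max_stiff;     // max d|F|/d(overlap), for dt control
};

// Smoothed colony top outline h(x): per-bin max of (z + r0) over rod
// endpoints and centers, then a centred moving average.
static void colony_outline(const NumericMatrix &st, double r0, double binw,
                           double x0, int nbin, std::vector<double> &hout) {
  std::vector<double> h(nbin, -1e30);
  const int n = st.nrow();
  for (int i = 0; i < n; ++i) {
    const double c = std::cos(st(i, 2)), s = std::sin(st(i, 2));
    const double hx = 0.5 * st(i, 3) * c, hz = 0.5 * st(i, 3) * s;
    const double px[3] = { st(i, 0) - hx, st(i, 0), st(i, 0) + hx };
    const double pz[3] = { st(i, 1) - hz, st(i, 1), st(i, 1) + hz };
    for (int k = 0; k < 3; ++k) {
      int b = (int)std::floor((px[k] - x0) / binw);
      if (b >= 0 && b < nbin && pz[k] + r0 > h[b]) h[b] = pz[k] + r0;
    }
  }
  hout.assign(nbin, -1e30);
  for (int b = 0; b < nbin; ++b) {
    double acc = 0.0; int cnt = 0;
    for (int k = -2; k <= 2; ++k) {
      int j = b + k;
      if (j >= 0 && j < nbin && h[j] > -1e29) { acc += h[j]; ++cnt; }
    }
    if (cnt > 0) hout[b] = acc / cnt;
  }
}

static void compute_all_forces(const NumericMatrix &st, double r0,
                               double k_cc, double k_wall, double k_surf,
                               double f_settle, Forces &F) {
  const int n = st.nrow();
  F.fx_cc.assign(n, 0.0); F.fz_cc.assign(n, 0.0); F.tq_cc.assign(n, 0.0);
  F.fx_ext.assign(n, 0.0); F.fz_ext.assign(n, 0.0); F.tq_ext.assign(n, 0.0);
  F.max_overlap = 0.0; F.max_stiff = 0.0;

  std::vector<double> ax(n), az(n), bx(n), bz(n); // segment endpoints
  double xmin = 1e30, xmax = -1e30;
  for (int i = 0; i < n; ++i) {
    const double c = std::cos(st(i, 2)), s = std::sin(st(i, 2));
    const double hx = 0.5 * st(i, 3) * c, hz = 0.5 * st(i, 3) * s;
    ax[i] = st(i, 0) - hx; az[i] = st(i, 1) - hz;
    bx[i] = st(i, 0) + hx; bz[i] = st(i, 1) + hz;
    if (st(i, 0) < xmin) xmin = st(i, 0);
    if (st(i, 0) > xmax) xmax = st(i, 0);
  }

  // cell-linked neighbour grid on centres
  double maxlen = 0.0;
  for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, st(i, 3));
  const double cell = std::max(maxlen + 2.0 * r0, 1.0);
  const double gx0 = xmin - cell;
  const int ngx = std::max(1, (int)std::ceil((xmax - gx0) / cell) + 2);
  double zmin = 1e30, zmax = -1e30;
  for (int i = 0; i < n; ++i) {
    zmin = std::min(zmin, st(i, 1)); zmax = std::max(zmax, st(i, 1));
  }
  const double gz0 = zmin - cell;
  const int ngz = std::max(1, (int)std::ceil((zmax - gz0) / cell) + 2);
  std::vector<int> head((size_t)ngx * ngz, -1), nxt(n, -1);
  std::vector<int> cix(n), ciz(n);
  for (int i = 0; i < n; ++i) {
    int bx_ = std::min(ngx - 1, std::max(0, (int)((st(i, 0) - gx0) / cell)));
    int bz_ = std::min(ngz - 1, std::max(0, (int)((st(i, 1) - gz0) / cell)));
    cix[i] = bx_; ciz[i] = bz_;
    const size_t b = (size_t)bz_ * ngx + bx_;
    nxt[i] = head[b]; head[b] = i;
  }

  const double two_r0 = 2.0 * r0;
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      const int zz = ciz[i] + dz;
      if (zz < 0 || zz >= ngz) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = cix[i] + dx;
        if (xx < 0 || xx >= ngx) continue;
        for (int j = head[(size_t)zz * ngx + xx]; j != -1; j = nxt[j]) {
          if (j <= i) continue;
          // bounding-circle reject before the exact segment test
          const double ddx = st(i, 0) - st(j, 0);
          const double ddz = st(i, 1) - st(j, 1);
          const double reach = 0.5 * (st(i, 3) + st(j, 3)) + two_r0;
          if (ddx * ddx + ddz * ddz > reach * reach) continue;
          double s, t;
          seg_seg_closest(ax[i], az[i], bx[i] - ax[i], bz[i] - az[i],
                          ax[j], az[j], bx[j] - ax[j], bz[j] - az[j], s, t);
          const double cix_ = ax[i] + s * (bx[i] - ax[i]);
          const double ciz_ = az[i] + s * (bz[i] - az[i]);
          const double cjx_ = ax[j] + t * (bx[j] - ax[j]);
          const double cjz_ = az[j] + t * (bz[j] - az[j]);
          double nx = cix_ - cjx_, nz = ciz_ - cjz_;
          double d = std::sqrt(nx * nx + nz * nz);
          if (d >= two_r0) continue;
          if (d < 1e-9) { // coincident closest points: push apart along z
            nx = 0.0; nz = 1.0; d = 1e-9;
          } else { nx /= d; nz /= d; }
          const double ov = two_r0 - d;
          const double fmag = k_cc * ov * std::sqrt(ov);
          if (ov > F.max_overlap) F.max_overlap = ov;
          const double st_ = 1.5 * k_cc * std::sqrt(ov);
          if (st_ > F.max_stiff) F.max_stiff = st_;
          const double fx = fmag * nx, fz = fmag * nz;
          // contact point midway between surface points
          const double px = 0.5 * (cix_ + cjx_), pz = 0.5 * (ciz_ + cjz_);
          F.fx_cc[i] += fx; F.fz_cc[i] += fz;
          F.tq_cc[i] += (px - st(i, 0)) * fz - (pz - st(i, 1)) * fx;
          F.fx_cc[j] -= fx; F.fz_cc[j] -= fz;
          F.tq_cc[j] -= (px - st(j, 0)) * fz - (pz - st(j, 1)) * fx;
        }
      }
    }
  }

  // agar contact (half-space z < 0), sampled at both poles and the centre
  for (int i = 0; i < n; ++i) {
    const double px[3] = { ax[i], st(i, 0), bx[i] };
    const double pz[3] = { az[i], st(i, 1), bz[i] };
    for (int k = 0; k < 3; ++k) {
      const double ov = r0 - pz[k];
      if (ov <= 0.0) continue;
      const double fz = k_wall * ov * std::sqrt(ov);
      const double st_ = 1.5 * k_wall * std::sqrt(ov);
      if (st_ > F.max_stiff) F.max_stiff = st_;
      F.fz_ext[i] += fz;
      F.tq_ext[i] += (px[k] - st(i, 0)) * fz;
    }
    // settling force, proportional to total rod length, applied at the centre
    F.fz_ext[i] -= f_settle * (st(i, 3) + 2.0 * r0);
  }

  // surface tension: pull protruding tops back to the smoothed outline
  if (k_surf > 0.0 && n > 1) {
    const double binw = 4.0;
    const double x0 = xmin - binw;
    const int nbin = std::max(1, (int)std::ceil((xmax - x0) / binw) + 2);
    std::vector<double> hout;
    colony_outline(st, r0, binw, x0, nbin, hout);
    const double tol = 0.5 * r0;
    for (int i = 0; i < n; ++i) {
      const double px[2] = { ax[i], bx[i] };
      const double pz[2] = { az[i], bz[i] };
      for (int k = 0; k < 2; ++k) {
        int b = (int)std::floor((px[k] - x0) / binw);
        if (b < 0 || b >= nbin || hout[b] < -1e29) continue;
        const double excess = (pz[k] + r0) - (hout[b] + tol);
        if (excess <= 0.0) continue;
        const double fz = -k_surf * excess;
        F.fz_ext[i] += fz;
        F.tq_ext[i] += (px[k] - st(i, 0)) * fz;
      }
    }
  }
}

// [[Rcpp::export(name = ".forces_cpp")]]
NumericMatrix forces_cpp(NumericMatrix state, double r0, double k_cc,
                         double k_wall, double k_surf, double f_settle) {
  Forces F;
  compute_all_forces(state, r0, k_cc, k_wall, k_surf, f_settle, F);
  const int n = state.nrow();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = F.fx_cc[i];  out(i, 1) = F.fz_cc[i];  out(i, 2) = F.tq_cc[i];
    out(i, 3) = F.fx_ext[i]; out(i, 4) = F.fz_ext[i]; out(i, 5) = F.tq_ext[i];
  }
  colnames(out) = CharacterVector::create("fx_cc", "fz_cc", "torque_cc",
                                          "fx_ext", "fz_ext", "torque_ext");
  out.attr("max_overlap") = F.max_overlap;
  out.attr("max_stiffness") = F.max_stiff;
  return out;
}

// Relax the configuration for `total_time` hours with adaptive explicit
// substeps bounded by the contact-stiffness stability limit.
// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix state, double r0, double k_cc, double k_wall,
               double k_surf, double f_settle, double drag,
               double total_time, double dt_max, double safety,
               int max_steps) {
  NumericMatrix st = clone(state);
  const int n = st.nrow();
  double t = 0.0;
  int steps = 0;
  Forces F;
  double minlen = 1e30;
  for (int i = 0; i < n; ++i) minlen = std::min(minlen, st(i, 3) + 2.0 * r0);
  const double halfpi = M_PI / 2.0;
  while (t < total_time && steps < max_steps) {
    compute_all_forces(st, r0, k_cc, k_wall, k_surf, f_settle, F);
    double dt = dt_max;
    if (F.max_stiff > 0.0) {
      const double bound = safety * drag * minlen / F.max_stiff;
      if (bound < dt) dt = bound;
    }
    if (t + dt > total_time) dt = total_time - t;
    for (int i = 0; i < n; ++i) {
      const double L = st(i, 3) + 2.0 * r0;
      const double zeta = drag * L;
      const double zrot = drag * L * L * L / 12.0;
      st(i, 0) += dt * (F.fx_cc[i] + F.fx_ext[i]) / zeta;
      st(i, 1) += dt * (F.fz_cc[i] + F.fz_ext[i]) / zeta;
      double a = st(i, 2) + dt * (F.tq_cc[i] + F.tq_ext[i]) / zrot;
      while (a > halfpi) a -= M_PI;
      while (a < -halfpi) a += M_PI;
      st(i, 2) = a;
    }
    t += dt;
    ++steps;
  }
  return List::create(_["state"] = st, _["time_advanced"] = t,
                      _["n_steps"] = steps,
                      _["max_overlap"] = F.max_overlap);
}
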