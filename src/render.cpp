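// Ray-cast DRR renderers over a labelled attenuation volume.
//
// Two integrators: an exact voxel intersection-length traversal (Siddon-style)
// and a fixed-step sampling integrator (trilinear attenuation, nearest label).
// Per-structure channels and the composite are accumulated in one traversal,
// so channel-sum == composite holds by construction for both integrators up to
// floating-point summation order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Grid {
  const double* mu;
  const int* lab;
  int nx, ny, nz;
};

inline double mu_at(const Grid& g, int i, int j, int k) {
  return g.mu[i + g.nx * (j + g.ny * k)];
}
inline int lab_at(const Grid& g, int i, int j, int k) {
  return g.lab[i + g.nx * (j + g.ny * k)];
}

// trilinear interpolation of mu at continuous index position p (voxel centers
// at integer+0.5); out-of-grid support clamps to the edge sample
inline double mu_tri(const Grid& g, double px, double py, double pz) {
  double fx = px - 0.5, fy = py - 0.5, fz = pz - 0.5;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double wx = fx - i0, wy = fy - j0, wz = fz - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = std::min(std::max(i0 + di, 0), g.nx - 1);
        int j = std::min(std::max(j0 + dj, 0), g.ny - 1);
        int k = std::min(std::max(k0 + dk, 0), g.nz - 1);
        double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
        acc += w * mu_at(g, i, j, k);
      }
  return acc;
}

// clip parametric ray A + t*(B-A), t in [0,1], to the index box [0,n]^3
inline bool clip_box(const arma::vec3& A, const arma::vec3& dir,
                     const double n[3], double& tmin, double& tmax) {
  tmin = 0.0; tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::abs(dir[a]) < 1e-12) {
      if (A[a] < 0.0 || A[a] > n[a]) return false;
    } else {
      double t1 = (0.0 - A[a]) / dir[a];
      double t2 = (n[a] - A[a]) / dir[a];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
    }
  }
  return tmin < tmax;
}

void integrate_exact(const Grid& g, const arma::vec3& A, const arma::vec3& B,
                     double L, double* comp, double* chan, int nch,
                     int pix, int npix) {
  arma::vec3 dir = B - A;
  const double nbox[3] = {(double)g.nx, (double)g.ny, (double)g.nz};
  double tmin, tmax;
  if (!clip_box(A, dir, nbox, tmin, tmax)) return;
  const double eps = 1e-10;
  arma::vec3 p = A + (tmin + eps) * dir;
  int iv[3];
  int dims[3] = {g.nx, g.ny, g.nz};
  for (int a = 0; a < 3; ++a)
    iv[a] = std::min(std::max((int)std::floor(p[a]), 0), dims[a] - 1);
  double tnext[3];
  int stp[3];
  double tdelta[3];
  for (int a = 0; a < 3; ++a) {
    if (dir[a] > eps) {
      stp[a] = 1;
      tdelta[a] = 1.0 / dir[a];
      tnext[a] = ((iv[a] + 1) - A[a]) / dir[a];
    } else if (dir[a] < -eps) {
      stp[a] = -1;
      tdelta[a] = -1.0 / dir[a];
      tnext[a] = (iv[a] - A[a]) / dir[a];
    } else {
      stp[a] = 0;
      tdelta[a] = 0.0;
      tnext[a] = std::numeric_limits<double>::infinity();
    }
  }
  double tcur = tmin;
  while (tcur < tmax - eps) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double tn = std::min(tnext[ax], tmax);
    double seg = (tn - tcur) * L;
    if (seg > 0) {
      double m = mu_at(g, iv[0], iv[1], iv[2]);
      if (m != 0.0) {
        comp[pix] += m * seg;
        int l = lab_at(g, iv[0], iv[1], iv[2]);
        if (l >= 1 && l <= nch) chan[pix + npix * (l - 1)] += m * seg;
      }
    }
    if (tnext[ax] >= tmax) break;
    tcur = tn;
    iv[ax] += stp[ax];
    if (iv[ax] < 0 || iv[ax] >= dims[ax]) break;
    tnext[ax] += tdelta[ax];
  }
}

void integrate_sampled(const Grid& g, const arma::vec3& A, const arma::vec3& B,
                       double L, double step_mm, double* comp, double* chan,
                       int nch, int pix, int npix, bool trilinear) {
  arma::vec3 dir = B - A;
  const double nbox[3] = {(double)g.nx, (double)g.ny, (double)g.nz};
  double tmin, tmax;
  if (!clip_box(A, dir, nbox, tmin, tmax)) return;
  double seglen = (tmax - tmin) * L;
  int nsteps = std::max(1, (int)std::ceil(seglen / step_mm));
  double ds = seglen / nsteps;
  int dims[3] = {g.nx, g.ny, g.nz};
  for (int q = 0; q < nsteps; ++q) {
    double t = tmin + (tmax - tmin) * (q + 0.5) / nsteps;
    arma::vec3 p = A + t * dir;
    int i = std::min(std::max((int)std::floor(p[0]), 0), dims[0] - 1);
    int j = std::min(std::max((int)std::floor(p[1]), 0), dims[1] - 1);
    int k = std::min(std::max((int)std::floor(p[2]), 0), dims[2] - 1);
    double m = trilinear ? mu_tri(g, p[0], p[1], p[2]) : mu_at(g, i, j, k);
    if (m != 0.0) {
      comp[pix] += m * ds;
      int l = lab_at(g, i, j, k);
      if (l >= 1 && l <= nch) chan[pix + npix * (l - 1)] += m * ds;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List render_cpp(NumericVector mu, IntegerVector lab, IntegerVector dims,
                NumericVector spacing, NumericMatrix rot, NumericVector trans,
                int model, double d, int nu, int nv, double pitch,
                int nch, int mode, double step_mm, bool trilinear) {
  Grid g{REAL(mu), INTEGER(lab), dims[0], dims[1], dims[2]};
  arma::mat33 R;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R(a, b) = rot(a, b);
  arma::vec3 t{trans[0], trans[1], trans[2]};
  arma::vec3 half{0.5 * dims[0] * spacing[0], 0.5 * dims[1] * spacing[1],
                  0.5 * dims[2] * spacing[2]};
  arma::vec3 sp{spacing[0], spacing[1], spacing[2]};

  NumericMatrix comp(nv, nu);
  NumericVector chan(nv * nu * nch);
  chan.attr("dim") = IntegerVector::create(nv, nu, nch);
  double* cp = REAL(comp);
  double* ch = REAL(chan);
  const int npix = nv * nu;

  for (int iu = 0; iu < nu; ++iu) {
    for (int iv = 0; iv < nv; ++iv) {
      double xu = (iu + 0.5 - 0.5 * nu) * pitch;
      double yv = (0.5 * nv - iv - 0.5) * pitch;
      arma::vec3 S, D{xu, yv, d};
      if (model == 1) {            // pinhole: point source at the origin
        S = {0.0, 0.0, 0.0};
      } else {                     // parallel beam along +z
        S = {xu, yv, 0.0};
      }
      // into volume index space
      arma::vec3 Sv = (R.t() * (S - t) + half) / sp;
      arma::vec3 Dv = (R.t() * (D - t) + half) / sp;
      double L = arma::norm(D - S);
      int pix = iv + nv * iu;
      if (mode == 0)
        integrate_exact(g, Sv, Dv, L, cp, ch, nch, pix, npix);
      else
        integrate_sampled(g, Sv, Dv, L, step_mm, cp, ch, nch, pix, npix,
                          trilinear);
    }
  }
  return List::create(_["composite"] = comp, _["channels"] = chan);
}
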