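#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bloch-vector propagation of spin-locked magnetization for a two-site
// orientational exchange under MAS. State = (Mx,My,Mz) conditional on each
// site (6 components). Per time step: exact rotation about the effective
// field of each site (Rodrigues), with symmetric exchange mixing applied as
// a Strang split (half step either side). Returns the lock-axis (x)
// magnetization summed over sites, sampled at rotor-period boundaries.

static inline void rotate_about(double wx, double wz, double dt,
                                double &mx, double &my, double &mz) {
  // effective field (wx, 0, wz); rotate M by angle -|w|dt about its axis
  double w = std::sqrt(wx * wx + wz * wz);
  if (w * dt < 1e-14) return;
  double ux = wx / w, uz = wz / w;
  double th = w * dt;
  double c = std::cos(th), s = std::sin(th), omc = 1.0 - c;
  // Rodrigues for axis (ux, 0, uz), angle th (sign convention immaterial
  // for the decay rate)
  double rxx = c + ux * ux * omc, rxy = -uz * s, rxz = ux * uz * omc;
  double ryx = uz * s,            ryy = c,       ryz = -ux * s;
  double rzx = ux * uz * omc,     rzy = ux * s,  rzz = c + uz * uz * omc;
  double nx = rxx * mx + rxy * my + rxz * mz;
  double ny = ryx * mx + ryy * my + ryz * mz;
  double nz = rzx * mx + rzy * my + rzz * mz;
  mx = nx; my = ny; mz = nz;
}

// [[Rcpp::export]]
NumericVector propagate_jump_mx(NumericVector dw1, NumericVector dw2,
                                double omega1, double dt, double k_ex,
                                int n_periods) {
  int n_steps = dw1.size();
  if (dw2.size() != n_steps) stop("site offset arrays differ in length");
  // conditional magnetizations, equal initial populations along the lock axis
  double m1x = 0.5, m1y = 0.0, m1z = 0.0;
  double m2x = 0.5, m2y = 0.0, m2z = 0.0;
  // symmetric two-site exchange over half a step:
  // exp(K dt/2): stay = (1+e)/2, move = (1-e)/2 with e = exp(-2 k dt/2)
  double e = std::exp(-k_ex * dt);
  double stay = 0.5 * (1.0 + e), move = 0.5 * (1.0 - e);
  NumericVector out(n_periods + 1);
  out[0] = m1x + m2x;
  for (int p = 0; p < n_periods; ++p) {
    for (int s = 0; s < n_steps; ++s) {
      double t;
      // half exchange
      t = m1x; m1x = stay * m1x + move * m2x; m2x = stay * m2x + move * t;
      t = m1y; m1y = stay * m1y + move * m2y; m2y = stay * m2y + move * t;
      t = m1z; m1z = stay * m1z + move * m2z; m2z = stay * m2z + move * t;
      // site rotations
      rotate_about(omega1, dw1[s], dt, m1x, m1y, m1z);
      rotate_about(omega1, dw2[s], dt, m2x, m2y, m2z);
      // half exchange
      t = m1x; m1x = stay * m1x + move * m2x; m2x = stay * m2x + move * t;
      t = m1y; m1y = stay * m1y + move * m2y; m2y = stay * m2y + move * t;
      t = m1z; m1z = stay * m1z + move * m2z; m2z = stay * m2z + move * t;
    }
    out[p + 1] = m1x + m2x;
  }
  return out;
}
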