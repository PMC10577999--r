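#include <Rcpp.h>
using namespace Rcpp;

// Inverse-CDF draw from the zero-mean Laplace law parameterized by its
// standard deviation sigma (scale b = sigma/sqrt(2)).  Uses R's global
// uniform stream so that set.seed() on the R side controls everything.
static inline double rlaplace_sd1(double sigma) {
  double u = unif_rand() - 0.5;
  double b = sigma * M_SQRT1_2;
  double s = (u < 0.0) ? -1.0 : 1.0;
  return -b * s * std::log(1.0 - 2.0 * std::fabs(u));
}

// Discrete Langevin update in the square arena |x|,|y| <= L/2.
//
// Per step, in this order (draw order matters for reproducibility):
//   1. draw q_T then q_L;
//   2. if the previous step ended on a wall, reflect the sign of q_T so the
//      turn points away from that wall (per contacted wall, in the fixed
//      order +x, -x, +y, -y; the last applicable wall wins at corners);
//   3. propose x + v*dt; compute force from (v, heading); update velocity;
//   4. stop mode: if the proposal exits the open arena, clamp to the nearest
//      boundary point and zero the exiting normal velocity component(s);
//   5. update heading from the new velocity whenever the new speed is > 0.
//
// init = (x, y, vx, vy, hx, hy) with (hx, hy) a unit heading.
// [[Rcpp::export]]
List cpp_simulate_2d(int n_steps, double dt, double tau_D, double v0,
                     double sigma_T, double sigma_L, double L, bool periodic,
                     NumericVector init) {
  NumericMatrix pos(n_steps + 1, 2);
  double x = init[0], y = init[1], vx = init[2], vy = init[3];
  double hx = init[4], hy = init[5];
  const double half = L / 2.0;
  const double tol = 1e-12;
  int wall_contacts = 0;
  pos(0, 0) = x;
  pos(0, 1) = y;
  for (int i = 0; i < n_steps; i++) {
    double eTx = -hy, eTy = hx;  // z-hat cross heading (left of travel)
    double qT = rlaplace_sd1(sigma_T);
    double qL = rlaplace_sd1(sigma_L);
    if (!periodic) {
      // wall flags from the current position (projection lands exactly on
      // +-L/2, so the flag persists until a step lands strictly inside)
      double req = 0.0;
      if (x >= half)  { double d =  eTx; if (std::fabs(d) > tol) req = (d < 0.0) ? 1.0 : -1.0; }
      if (x <= -half) { double d = -eTx; if (std::fabs(d) > tol) req = (d < 0.0) ? 1.0 : -1.0; }
      if (y >= half)  { double d =  eTy; if (std::fabs(d) > tol) req = (d < 0.0) ? 1.0 : -1.0; }
      if (y <= -half) { double d = -eTy; if (std::fabs(d) > tol) req = (d < 0.0) ? 1.0 : -1.0; }
      if (req != 0.0) qT = req * std::fabs(qT);
    }
    double xp = x + vx * dt, yp = y + vy * dt;
    double sp = std::sqrt(vx * vx + vy * vy);
    double dx = (sp > 0.0) ? vx / sp : hx;
    double dy = (sp > 0.0) ? vy / sp : hy;
    double Fx = -vx / tau_D + (v0 / tau_D) * dx;
    double Fy = -vy / tau_D + (v0 / tau_D) * dy;
    double nvx = vx + Fx * dt + qT * eTx + qL * hx;
    double nvy = vy + Fy * dt + qT * eTy + qL * hy;
    if (!periodic) {
      bool outx = std::fabs(xp) > half, outy = std::fabs(yp) > half;
      if (outx || outy) {
        wall_contacts++;
        if (outx) { xp = (xp > 0.0) ? half : -half; nvx = 0.0; }
        if (outy) { yp = (yp > 0.0) ? half : -half; nvy = 0.0; }
      }
    }
    x = xp;
    y = yp;
    vx = nvx;
    vy = nvy;
    double ns = std::sqrt(vx * vx + vy * vy);
    if (ns > 0.0) { hx = vx / ns; hy = vy / ns; }
    pos(i + 1, 0) = x;
    pos(i + 1, 1) = y;
  }
  return List::create(_["positions"] = pos,
                      _["wall_contacts"] = wall_contacts);
}

// One-dimensional reduction: v <- v + dt*(v0*sign(v) - v)/tau_D + q_L with
// stop walls at +-L/2 (velocity zeroed on contact) and the first post-contact
// impulse directed inward.
// [[Rcpp::export]]
List cpp_simulate_1d(int n_steps, double dt, double tau_D, double v0,
                     double sigma_L, double L, double x0, double v0_init) {
  NumericVector pos(n_steps + 1);
  double x = x0, v = v0_init;
  const double half = L / 2.0;
  int wall_contacts = 0;
  pos[0] = x;
  for (int i = 0; i < n_steps; i++) {
    double q = rlaplace_sd1(sigma_L);
    if (x >= half) q = -std::fabs(q);
    else if (x <= -half) q = std::fabs(q);
    double xp = x + v * dt;
    double sg = (v > 0.0) - (v < 0.0);
    double nv = v + dt * (v0 * sg - v) / tau_D + q;
    if (std::fabs(xp) > half) {
      wall_contacts++;
      xp = (xp > 0.0) ? half : -half;
      nv = 0.0;
    }
    x = xp;
    v = nv;
    pos[i + 1] = x;
  }
  return List::create(_["positions"] = pos,
                      _["wall_contacts"] = wall_contacts);
}
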