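// Langevin dynamics with optional well-tempered metadynamics bias on the
// Mueller-Brown potential (or a harmonic/flat reference potential for
// validation runs). The integrator is the Bussi-Parrinello scheme: an exact
// Ornstein-Uhlenbeck half-step on the velocity, a velocity-Verlet kick-drift-
// kick, and a second OU half-step. Masses are 1 and k_B = 1 throughout.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <cstdint>
using namespace Rcpp;

namespace {

// Deterministic normal deviates: Box-Muller on mt19937_64 uniforms, so that
// trajectories are bit-reproducible across platforms (std::normal_distribution
// is implementation-defined).
struct Rng {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {
    // (0, 1), never exactly 0
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct MBPot {
  double A[4], a[4], b[4], c[4], x0[4], y0[4];
  double energy(double x, double y) const {
    double u = 0.0;
    for (int j = 0; j < 4; ++j) {
      double dx = x - x0[j], dy = y - y0[j];
      u += A[j] * std::exp(a[j] * dx * dx + b[j] * dx * dy + c[j] * dy * dy);
    }
    return u;
  }
  void grad(double x, double y, double& gx, double& gy) const {
    gx = 0.0; gy = 0.0;
    for (int j = 0; j < 4; ++j) {
      double dx = x - x0[j], dy = y - y0[j];
      double e = A[j] * std::exp(a[j] * dx * dx + b[j] * dx * dy + c[j] * dy * dy);
      gx += e * (2.0 * a[j] * dx + b[j] * dy);
      gy += e * (b[j] * dx + 2.0 * c[j] * dy);
    }
  }
};

// Sum-of-hills bias. Hills are diagonal Gaussians; contributions with
// exponent below -30 are dropped (relative error < 1e-13).
struct Hills {
  std::vector<double> cx, cy, h;
  double wx2, wy2;  // 2 * width^2
  double value(double x, double y) const {
    double v = 0.0;
    for (size_t i = 0; i < cx.size(); ++i) {
      double dx = x - cx[i], dy = y - cy[i];
      double ex = -(dx * dx / wx2 + dy * dy / wy2);
      if (ex > -30.0) v += h[i] * std::exp(ex);
    }
    return v;
  }
  void force(double x, double y, double& fx, double& fy) const {
    // returns -dV/dx, -dV/dy
    fx = 0.0; fy = 0.0;
    for (size_t i = 0; i < cx.size(); ++i) {
      double dx = x - cx[i], dy = y - cy[i];
      double ex = -(dx * dx / wx2 + dy * dy / wy2);
      if (ex > -30.0) {
        double e = h[i] * std::exp(ex);
        fx += e * 2.0 * dx / wx2;
        fy += e * 2.0 * dy / wy2;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_run_langevin")]]
List cpp_run_langevin(NumericVector start,
                      NumericVector A, NumericVector a, NumericVector b,
                      NumericVector c, NumericVector x0, NumericVector y0,
                      int potential,       // 0 = Mueller-Brown, 1 = harmonic
                      double kappa,        // harmonic spring constant
                      double temperature, double friction, double dt,
                      double nsteps_d, int save_stride, double seed,
                      bool use_bias, bool gamma_inf, double gamma,
                      double height0, double width_x, double width_y,
                      int pace, NumericVector grid_bounds, IntegerVector grid_shape,
                      int ct_stride) {
  const long long nsteps = static_cast<long long>(nsteps_d);
  MBPot pot;
  for (int j = 0; j < 4; ++j) {
    pot.A[j] = A[j]; pot.a[j] = a[j]; pot.b[j] = b[j];
    pot.c[j] = c[j]; pot.x0[j] = x0[j]; pot.y0[j] = y0[j];
  }
  Rng rng(static_cast<uint64_t>(seed));
  const double beta = 1.0 / temperature;

  // bias bookkeeping
  Hills hills;
  hills.wx2 = 2.0 * width_x * width_x;
  hills.wy2 = 2.0 * width_y * width_y;
  const int ngx = grid_shape[0], ngy = grid_shape[1];
  const double gxlo = grid_bounds[0], gxhi = grid_bounds[1];
  const double gylo = grid_bounds[2], gyhi = grid_bounds[3];
  const double dgx = (gxhi - gxlo) / (ngx - 1), dgy = (gyhi - gylo) / (ngy - 1);
  std::vector<double> vgrid;
  if (use_bias) vgrid.assign(static_cast<size_t>(ngx) * ngy, 0.0);
  double ct = 0.0;
  std::vector<double> hill_t, hill_x, hill_y, hill_h;

  auto add_hill_to_grid = [&](double hx, double hy, double hh) {
    // only touch grid nodes within the -30 exponent cutoff
    double rx = std::sqrt(30.0 * hills.wx2), ry = std::sqrt(30.0 * hills.wy2);
    int i0 = std::max(0, (int)std::ceil((hx - rx - gxlo) / dgx));
    int i1 = std::min(ngx - 1, (int)std::floor((hx + rx - gxlo) / dgx));
    int j0 = std::max(0, (int)std::ceil((hy - ry - gylo) / dgy));
    int j1 = std::min(ngy - 1, (int)std::floor((hy + ry - gylo) / dgy));
    for (int i = i0; i <= i1; ++i) {
      double dx = gxlo + i * dgx - hx;
      for (int j = j0; j <= j1; ++j) {
        double dy = gylo + j * dgy - hy;
        double ex = -(dx * dx / hills.wx2 + dy * dy / hills.wy2);
        if (ex > -30.0) vgrid[(size_t)i * ngy + j] += hh * std::exp(ex);
      }
    }
  };

  auto compute_ct = [&]() {
    // c(t) = beta^-1 log[ int e^{g*beta*V/(g-1)} / int e^{beta*V/(g-1)} ]
    // by trapezoidal quadrature (edge nodes weighted 1/2, corners 1/4; the
    // common cell area cancels in the ratio); gamma -> inf gives
    // beta^-1 log[ <e^{beta*V}> ].
    double fac_num, fac_den;
    if (gamma_inf) { fac_num = beta; fac_den = 0.0; }
    else { fac_num = gamma * beta / (gamma - 1.0); fac_den = beta / (gamma - 1.0); }
    double vmax = 0.0;
    for (double v : vgrid) if (v > vmax) vmax = v;
    double snum = 0.0, sden = 0.0;
    for (int i = 0; i < ngx; ++i) {
      double wi = (i == 0 || i == ngx - 1) ? 0.5 : 1.0;
      for (int j = 0; j < ngy; ++j) {
        double wgt = wi * ((j == 0 || j == ngy - 1) ? 0.5 : 1.0);
        double v = vgrid[(size_t)i * ngy + j];
        snum += wgt * std::exp(fac_num * (v - vmax));
        sden += wgt * std::exp(fac_den * (v - vmax));
      }
    }
    return (1.0 / beta) * ((fac_num - fac_den) * vmax + std::log(snum) - std::log(sden));
  };

  // force at current position
  auto force = [&](double x, double y, double& fx, double& fy) {
    if (potential == 0) {
      pot.grad(x, y, fx, fy);
      fx = -fx; fy = -fy;
    } else {
      fx = -kappa * x; fy = -kappa * y;
    }
    if (use_bias) {
      double bx, by;
      hills.force(x, y, bx, by);
      fx += bx; fy += by;
    }
  };

  double x = start[0], y = start[1];
  double vx = 0.0, vy = 0.0;
  const double c1 = std::exp(-friction * dt / 2.0);
  const double c2 = std::sqrt(temperature * (1.0 - c1 * c1));

  long long nsave = nsteps / save_stride + 1;
  NumericVector out_t(nsave), out_x(nsave), out_y(nsave);
  NumericVector out_vx(nsave), out_vy(nsave), out_bias(nsave), out_ct(nsave);
  long long isave = 0;
  auto save_frame = [&](long long step) {
    out_t[isave] = step * dt;
    out_x[isave] = x; out_y[isave] = y;
    out_vx[isave] = vx; out_vy[isave] = vy;
    out_bias[isave] = use_bias ? hills.value(x, y) : 0.0;
    out_ct[isave] = ct;
    ++isave;
  };
  save_frame(0);

  double fx, fy;
  force(x, y, fx, fy);
  const double blow_x = std::max(std::abs(gxlo), std::abs(gxhi)) + 1.0;
  const double blow_y = std::max(std::abs(gylo), std::abs(gyhi)) + 1.0;

  for (long long step = 1; step <= nsteps; ++step) {
    if (c2 > 0.0 || c1 < 1.0) {
      vx = c1 * vx + c2 * rng.norm();
      vy = c1 * vy + c2 * rng.norm();
    }
    vx += 0.5 * dt * fx;
    vy += 0.5 * dt * fy;
    x += dt * vx;
    y += dt * vy;
    force(x, y, fx, fy);
    vx += 0.5 * dt * fx;
    vy += 0.5 * dt * fy;
    if (c2 > 0.0 || c1 < 1.0) {
      vx = c1 * vx + c2 * rng.norm();
      vy = c1 * vy + c2 * rng.norm();
    }
    if (!std::isfinite(x) || !std::isfinite(y) ||
        std::abs(x) > blow_x || std::abs(y) > blow_y) {
      stop("numerical blow-up at step %lld: position (%g, %g) left the domain",
           step, x, y);
    }
    if (use_bias && step % pace == 0) {
      double hh;
      if (gamma_inf) hh = height0;
      else hh = height0 * std::exp(-hills.value(x, y) / ((gamma - 1.0) * temperature));
      hills.cx.push_back(x); hills.cy.push_back(y); hills.h.push_back(hh);
      hill_t.push_back(step * dt); hill_x.push_back(x); hill_y.push_back(y);
      hill_h.push_back(hh);
      add_hill_to_grid(x, y, hh);
      if ((hills.cx.size() % (size_t)ct_stride) == 0) ct = compute_ct();
      force(x, y, fx, fy);  // bias changed under our feet
    }
    if (step % save_stride == 0) save_frame(step);
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["time"] = out_t, _["x"] = out_x, _["y"] = out_y,
      _["vx"] = out_vx, _["vy"] = out_vy,
      _["bias"] = out_bias, _["ct"] = out_ct,
      _["hill_time"] = wrap(hill_t), _["hill_x"] = wrap(hill_x),
      _["hill_y"] = wrap(hill_y), _["hill_height"] = wrap(hill_h));
}
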