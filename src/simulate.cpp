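// Euler-Heun SDE integration and return-time recording for the packaged
// models.  Uses R's RNG (norm_rand) so runs are reproducible under
// set.seed().  The phase along a trajectory is read from bicubic
// (Catmull-Rom) interpolants of cos(phase) and sin(phase), recombined with
// atan2 so the 2*pi branch cut never appears.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// drift fields of the packaged models; pars layout documented per case
static inline void drift(int code, const double* pars, double x, double y,
                         double& fx, double& fy) {
  switch (code) {
  case 1:  // linear: pars = A column-major
    fx = pars[0] * x + pars[2] * y;
    fy = pars[1] * x + pars[3] * y;
    break;
  case 2: {  // Wilson-Cowan: c1 c2 c3 c4 a_e a_i th_e th_i P Q
    double ue = pars[0] * x - pars[1] * y + pars[8];
    double ui = pars[2] * x - pars[3] * y + pars[9];
    fx = -x + 1.0 / (1.0 + std::exp(-pars[4] * (ue - pars[6])));
    fy = -y + 1.0 / (1.0 + std::exp(-pars[5] * (ui - pars[7])));
    break;
  }
  case 3:  // Van der Pol
    fx = -y + x - x * x * x;
    fy = x;
    break;
  case 4: {  // heteroclinic: pars = alpha
    double a = pars[0];
    fx =  std::cos(x) * std::sin(y) + a * std::sin(2.0 * x);
    fy = -std::sin(x) * std::cos(y) + a * std::sin(2.0 * y);
    break;
  }
  default:
    stop("unknown model code");
  }
}

// reflect into [lo, hi]
static inline double reflect1(double v, double lo, double hi) {
  double w = hi - lo;
  if (v < lo) v = lo + (lo - v);
  if (v > hi) v = hi - (v - hi);
  // a huge step could overshoot twice; fold defensively (period 2w)
  if (v < lo || v > hi) {
    double u = (v - lo) / (2.0 * w);
    u -= std::floor(u);
    u *= 2.0 * w;
    v = (u <= w) ? lo + u : lo + 2.0 * w - u;
  }
  return v;
}

// Catmull-Rom cubic kernel evaluation on one axis
static inline void cubw(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

struct Interp2 {
  const double* z;  // N x M column-major
  int N, M;
  double x0, y0, dx, dy;
  // bicubic with clamped indices (nearest-value extension at the border)
  double operator()(double x, double y) const {
    double tx = (x - x0) / dx, ty = (y - y0) / dy;
    int i1 = (int)std::floor(tx), j1 = (int)std::floor(ty);
    double fx = tx - i1, fy = ty - j1;
    if (i1 < 0) { i1 = 0; fx = 0.0; }
    if (i1 > N - 2) { i1 = N - 2; fx = 1.0; }
    if (j1 < 0) { j1 = 0; fy = 0.0; }
    if (j1 > M - 2) { j1 = M - 2; fy = 1.0; }
    double wx[4], wy[4];
    cubw(fx, wx); cubw(fy, wy);
    double s = 0.0;
    for (int b = 0; b < 4; ++b) {
      int j = j1 - 1 + b;
      if (j < 0) j = 0;
      if (j > M - 1) j = M - 1;
      double row = 0.0;
      for (int a = 0; a < 4; ++a) {
        int i = i1 - 1 + a;
        if (i < 0) i = 0;
        if (i > N - 1) i = N - 1;
        row += wx[a] * z[i + (size_t)N * j];
      }
      s += wy[b] * row;
    }
    return s;
  }
};

// one Euler-Heun step with additive noise g (2x2, column-major)
static inline void heun_step(int code, const double* pars, const double* g,
                             double dt, double sdt, double& x, double& y) {
  double f1x, f1y, f2x, f2y;
  double z1 = norm_rand(), z2 = norm_rand();
  double nx = (g[0] * z1 + g[2] * z2) * sdt;
  double ny = (g[1] * z1 + g[3] * z2) * sdt;
  drift(code, pars, x, y, f1x, f1y);
  double xp = x + f1x * dt + nx;
  double yp = y + f1y * dt + ny;
  drift(code, pars, xp, yp, f2x, f2y);
  x += 0.5 * (f1x + f2x) * dt + nx;
  y += 0.5 * (f1y + f2y) * dt + ny;
}

// [[Rcpp::export]]
List cpp_simulate_paths(int code, NumericVector pars, NumericVector gmat,
                        NumericVector x0, double dt, int nsteps, int npaths,
                        int save_every, NumericVector domain, bool reflect) {
  RNGScope scope;
  const double* p = pars.begin();
  const double* g = gmat.begin();
  double sdt = std::sqrt(dt);
  int nsave = nsteps / save_every + 1;
  NumericVector X(npaths * nsave), Y(npaths * nsave);
  double lo1 = domain[0], hi1 = domain[1], lo2 = domain[2], hi2 = domain[3];
  for (int path = 0; path < npaths; ++path) {
    double x = x0[0], y = x0[1];
    X[path] = x; Y[path] = y;
    int isave = 1;
    for (int k = 1; k <= nsteps; ++k) {
      heun_step(code, p, g, dt, sdt, x, y);
      if (reflect) { x = reflect1(x, lo1, hi1); y = reflect1(y, lo2, hi2); }
      if (!std::isfinite(x) || !std::isfinite(y))
        stop("path blow-up (NaN) at step %d of path %d", k, path + 1);
      if (k % save_every == 0) {
        X[path + (size_t)npaths * isave] = x;
        Y[path + (size_t)npaths * isave] = y;
        ++isave;
      }
    }
  }
  X.attr("dim") = IntegerVector::create(npaths, nsave);
  Y.attr("dim") = IntegerVector::create(npaths, nsave);
  return List::create(_["x"] = X, _["y"] = Y);
}

// [[Rcpp::export]]
List cpp_return_times(int code, NumericVector pars, NumericVector gmat,
                      NumericVector cosP, NumericVector sinP,
                      int N, int M, NumericVector gx0y0, NumericVector gdxdy,
                      NumericVector x0, int npaths, double dt, int maxsteps,
                      NumericVector domain, bool reflect) {
  RNGScope scope;
  const double* p = pars.begin();
  const double* g = gmat.begin();
  Interp2 ic{cosP.begin(), N, M, gx0y0[0], gx0y0[1], gdxdy[0], gdxdy[1]};
  Interp2 is{sinP.begin(), N, M, gx0y0[0], gx0y0[1], gdxdy[0], gdxdy[1]};
  double sdt = std::sqrt(dt);
  double lo1 = domain[0], hi1 = domain[1], lo2 = domain[2], hi2 = domain[3];
  NumericVector times(npaths);
  int nonreturn = 0, clamped = 0, bigstep = 0;
  double twopi = 2.0 * M_PI;
  for (int path = 0; path < npaths; ++path) {
    double x = x0[0], y = x0[1];
    double ph_prev = std::atan2(is(x, y), ic(x, y));
    double acc = 0.0;
    double t = NA_REAL;
    for (int k = 1; k <= maxsteps; ++k) {
      heun_step(code, p, g, dt, sdt, x, y);
      if (reflect) { x = reflect1(x, lo1, hi1); y = reflect1(y, lo2, hi2); }
      if (!std::isfinite(x) || !std::isfinite(y))
        stop("path blow-up (NaN) at step %d of path %d", k, path + 1);
      if (x < lo1 || x > hi1 || y < lo2 || y > hi2) ++clamped;
      double ph = std::atan2(is(x, y), ic(x, y));
      double d = ph - ph_prev;
      if (d > M_PI) d -= twopi;
      if (d < -M_PI) d += twopi;
      if (std::fabs(d) > 2.5) ++bigstep;
      ph_prev = ph;
      double acc_new = acc + d;
      if (acc_new >= twopi) {
        // sub-step linear interpolation of the crossing time
        t = (k - 1) * dt + dt * (twopi - acc) / d;
        break;
      }
      acc = acc_new;
    }
    if (!std::isfinite(t)) { ++nonreturn; t = NA_REAL; }
    times[path] = t;
  }
  return List::create(_["times"] = times, _["nonreturn"] = nonreturn,
                      _["clamped"] = clamped, _["bigstep"] = bigstep);
}

// [[Rcpp::export]]
NumericVector cpp_interp2(NumericVector z, int N, int M,
                          NumericVector gx0y0, NumericVector gdxdy,
                          NumericVector x, NumericVector y) {
  Interp2 iz{z.begin(), N, M, gx0y0[0], gx0y0[1], gdxdy[0], gdxdy[1]};
  int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = iz(x[k], y[k]);
  return out;
}
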