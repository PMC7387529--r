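#include <Rcpp.h>
using namespace Rcpp;

// Hereditary convolution for spherical indentation of a power-law-rheology
// half-space (relaxation modulus E(t) = E1 * t^(-alpha)).
//
// During increasing/constant contact:
//   F(t) = pref * \int_0^t E(t - xi) d(delta^{3/2})/dxi dxi,
//   pref = 4 sqrt(R) / (3 (1 - nu^2)).
// During retraction the upper limit becomes the auxiliary time t1(t) defined
// by \int_{t1}^{t} E(t - xi) delta'(xi) dxi = 0 (Ting's condition).
//
// The depth history is piecewise linear between samples; the weakly singular
// kernel (t - xi)^(-alpha) is integrated analytically interval-by-interval
// against a piecewise-linear delta^{3/2}, so no pointwise evaluation at zero
// lag occurs. Because delta^{3/2} has unbounded curvature where delta -> 0,
// intervals with near-zero depth are subdivided on an internal graded grid
// (exact for the piecewise-linear depth) before the analytic quadrature.

static inline double kern_int(double t, double a, double b, double om) {
  // \int_a^b (t - xi)^(-alpha) dxi, om = 1 - alpha, requires a <= b <= t
  double ta = t - a;
  double tb = t - b;
  if (tb < 0.0) tb = 0.0;
  return (std::pow(ta, om) - std::pow(tb, om)) / om;
}

struct RefinedGrid {
  std::vector<double> xi;     // refined node times
  std::vector<double> gslope; // slope of delta^{3/2} per refined interval
};

static RefinedGrid refine_grid(const std::vector<double>& tt,
                               const std::vector<double>& dep) {
  int n = tt.size();
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) if (dep[i] > dmax) dmax = dep[i];
  RefinedGrid rg;
  rg.xi.push_back(tt[0]);
  std::vector<double> gg;
  gg.push_back(std::pow(std::max(dep[0], 0.0), 1.5));
  for (int j = 0; j + 1 < n; ++j) {
    double a = tt[j], b = tt[j + 1];
    double da = std::max(dep[j], 0.0), db = std::max(dep[j + 1], 0.0);
    double dmin = std::min(da, db);
    int m;
    if (dmin <= 0.05 * dmax) m = 48;       // curvature blows up near contact
    else if (dmin <= 0.2 * dmax) m = 8;
    else m = 2;
    bool grade_left = da < db;             // singular end of the interval
    for (int k = 1; k <= m; ++k) {
      double f = (double)k / m;
      if (m > 2) {
        // cubic grading: cluster sub-nodes toward the near-zero-depth end
        f = grade_left ? std::pow(f, 3.0) : 1.0 - std::pow(1.0 - f, 3.0);
      }
      double x = a + (b - a) * f;
      double d = da + (db - da) * ((x - a) / (b - a));
      if (k == m) { x = b; d = db; }
      rg.xi.push_back(x);
      gg.push_back(std::pow(std::max(d, 0.0), 1.5));
    }
  }
  int N = rg.xi.size();
  rg.gslope.resize(N - 1);
  for (int j = 0; j + 1 < N; ++j) {
    double h = rg.xi[j + 1] - rg.xi[j];
    rg.gslope[j] = h > 0 ? (gg[j + 1] - gg[j]) / h : 0.0;
  }
  return rg;
}

// \int_0^{upto} (t - xi)^(-alpha) d(delta^{3/2}) on the refined grid
static double conv_g(const RefinedGrid& rg, double t, double upto, double om) {
  double acc = 0.0;
  int N = rg.xi.size();
  for (int j = 0; j + 1 < N; ++j) {
    double a = rg.xi[j], b = rg.xi[j + 1];
    if (a >= upto) break;
    if (b > upto) b = upto;
    if (b <= a) continue;
    acc += rg.gslope[j] * kern_int(t, a, b, om);
  }
  return acc;
}

// Ting's t1 condition: \int_{t1}^{t} (t - xi)^(-alpha) delta'(xi) dxi
// (delta is piecewise linear on the original grid, so no refinement needed)
static double phi_t1(const std::vector<double>& tt,
                     const std::vector<double>& dslope,
                     double t, double t1, double om) {
  double acc = 0.0;
  int n = tt.size();
  for (int j = 0; j + 1 < n; ++j) {
    double a = tt[j], b = tt[j + 1];
    if (b <= t1) continue;
    if (a >= t) break;
    if (a < t1) a = t1;
    if (b > t) b = t;
    if (b <= a) continue;
    acc += dslope[j] * kern_int(t, a, b, om);
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector ting_force_cpp(NumericVector time, NumericVector depth,
                             double E1, double alpha, double tip_radius,
                             double nu) {
  int n = time.size();
  if (depth.size() != n) stop("time and depth must have equal length");
  if (alpha < 0.0 || alpha >= 1.0) stop("alpha must lie in [0, 1)");
  if (E1 <= 0.0) stop("E1 must be positive");
  double om = 1.0 - alpha;
  double pref = 4.0 * std::sqrt(tip_radius) / (3.0 * (1.0 - nu * nu));

  std::vector<double> tt(n), dep(n);
  double t0 = time[0];
  for (int i = 0; i < n; ++i) {
    tt[i] = time[i] - t0;             // history starts at contact
    dep[i] = depth[i] > 0.0 ? depth[i] : 0.0;
  }
  for (int i = 0; i + 1 < n; ++i) {
    if (tt[i + 1] <= tt[i]) stop("time must be strictly increasing");
  }

  // last sample of maximal depth = end of the increasing-contact phase
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) if (dep[i] > dmax) dmax = dep[i];
  int im = 0;
  for (int i = 0; i < n; ++i) if (dep[i] >= dmax * (1.0 - 1e-12)) im = i;

  std::vector<double> dslope(n > 1 ? n - 1 : 0);
  for (int j = 0; j + 1 < n; ++j) {
    dslope[j] = (dep[j + 1] - dep[j]) / (tt[j + 1] - tt[j]);
  }
  RefinedGrid rg = refine_grid(tt, dep);

  NumericVector force(n);
  for (int i = 1; i <= im; ++i) {
    force[i] = pref * E1 * conv_g(rg, tt[i], tt[i], om);
  }

  // retraction: t1 from Ting's condition. Because delta is piecewise linear,
  // phi(t1) is analytic within each interval, so the root is bracketed by a
  // downward interval walk and then solved in closed form.
  double hi0 = tt[im];
  for (int i = im + 1; i < n; ++i) {
    double t = tt[i];
    double acc = phi_t1(tt, dslope, t, hi0, om);   // phi at the upper bracket
    double t1;
    if (acc >= 0.0) {
      t1 = hi0;                       // contact still at its maximum extent
    } else {
      t1 = -1.0;
      int j0 = 0;
      while (j0 + 1 < n && tt[j0 + 1] < hi0) ++j0; // interval containing hi0
      for (int j = j0; j >= 0; --j) {
        double a = tt[j];
        double b = std::min(tt[j + 1], hi0);
        if (b <= a) continue;
        double seg = dslope[j] * kern_int(t, a, b, om);
        double phi_a = acc + seg;                  // acc == phi(b)
        if (phi_a > 0.0 && dslope[j] > 0.0) {
          // solve acc + dslope*((t-t1)^om - (t-b)^om)/om = 0 on [a, b]
          double rhs = std::pow(t - b, om) - om * acc / dslope[j];
          t1 = t - std::pow(rhs, 1.0 / om);
          if (t1 < a) t1 = a;
          if (t1 > b) t1 = b;
          break;
        }
        acc = phi_a;
      }
      if (t1 < 0.0) { force[i] = 0.0; hi0 = 0.0; continue; } // contact lost
      hi0 = t1;                       // enforce t1 non-increasing
    }
    double f = pref * E1 * conv_g(rg, t, t1, om);
    force[i] = f > 0.0 ? f : 0.0;
  }
  return force;
}
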