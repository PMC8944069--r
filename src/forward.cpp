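#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Compact radial basis functions and the stable inverse logit.
//
// A CRBF is a C-infinity bump with support |t - c| < w; the value at the
// support boundary is defined as 0 (the continuous limit), which also avoids
// the division by zero at |t - c| = w.
// ---------------------------------------------------------------------------

inline double crbf1(double t, double c, double w) {
  double s = (t - c) / w;
  double s2 = s * s;
  if (s2 >= 1.0) return 0.0;
  return std::exp(1.0 - 1.0 / (1.0 - s2));
}

// Two-branch logistic: the exponential is only ever applied to a
// non-positive argument, so there is no overflow for large |f|.
inline double invlogit1(double f) {
  if (f > 0.0) return 1.0 / (1.0 + std::exp(-f));
  double e = std::exp(f);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
NumericVector cpp_crbf(NumericVector t, double c, double w, double A) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = A * crbf1(t[i], c, w);
  return out;
}

// Excitations u(t, m) for all muscles on a time grid.
// A is n_muscles x n_nodes; centers length n_nodes.
// [[Rcpp::export]]
NumericMatrix cpp_excitations(NumericMatrix A, NumericVector centers,
                              double w, NumericVector t) {
  int nm = A.nrow(), nn = A.ncol(), nt = t.size();
  if (centers.size() != nn) stop("length(centers) must equal ncol(A)");
  NumericMatrix u(nt, nm);
  for (int m = 0; m < nm; ++m) {
    for (int k = 0; k < nt; ++k) {
      double f = 0.0;
      for (int i = 0; i < nn; ++i) f += A(m, i) * crbf1(t[k], centers[i], w);
      u(k, m) = invlogit1(f);
    }
  }
  return u;
}

// ---------------------------------------------------------------------------
// Hill-type muscle with rigid tendon and constant moment arm.
//
// Curve shapes (dimensionless, scaled by F_max):
//   active force-length  f_L(ln)  = exp(-((ln - 1)/0.45)^2)
//   force-velocity       f_V(vn)  = (1 + vn)/(1 - 4 vn)        vn in [-1, 0]
//                                 = 1 + 0.4 vn/(vn + 0.1333)   vn > 0
//                                 = 0                           vn <= -1
//   passive              f_PE(ln) = (exp(4 (ln-1)/0.6) - 1)/(exp(4) - 1), ln > 1
// with ln = l_fiber/l_opt and vn = v_fiber/(10 l_opt) (positive lengthening).
// f_V(0) = 1, f_V(-1) = 0, eccentric plateau 1.4.
// ---------------------------------------------------------------------------

inline double active_fl(double ln) {
  double d = (ln - 1.0) / 0.45;
  return std::exp(-d * d);
}

inline double force_vel(double vn) {
  if (vn <= -1.0) return 0.0;
  if (vn <= 0.0) return (1.0 + vn) / (1.0 - 4.0 * vn);
  return 1.0 + 0.4 * vn / (vn + 0.1333);
}

inline double passive_fl(double ln) {
  if (ln <= 1.0) return 0.0;
  return (std::exp(4.0 * (ln - 1.0) / 0.6) - 1.0) / (std::exp(4.0) - 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_muscle_curves(double ln, double vn) {
  return NumericVector::create(_["fl"] = active_fl(ln),
                               _["fv"] = force_vel(vn),
                               _["fpe"] = passive_fl(ln));
}

struct MusclePar {
  double fmax, lopt, lts, cosa, r, lmt0, tact, tdeact;
};

// muscle parameter matrix columns (fixed order, built in R):
// f_max, l_opt, l_ts, alpha0, r, l_mt0, tau_act, tau_deact
static std::vector<MusclePar> parse_muscles(const NumericMatrix& mp) {
  std::vector<MusclePar> mus(mp.nrow());
  for (int m = 0; m < mp.nrow(); ++m) {
    mus[m].fmax = mp(m, 0);
    mus[m].lopt = mp(m, 1);
    mus[m].lts = mp(m, 2);
    mus[m].cosa = std::cos(mp(m, 3));
    mus[m].r = mp(m, 4);
    mus[m].lmt0 = mp(m, 5);
    mus[m].tact = mp(m, 6);
    mus[m].tdeact = mp(m, 7);
  }
  return mus;
}

// Total muscle force for one muscle at state (theta, omega, a).
inline double muscle_force1(const MusclePar& mu, double theta, double omega,
                            double a) {
  double lmt = mu.lmt0 - mu.r * theta;
  double lf = (lmt - mu.lts) / mu.cosa;
  double floor_lf = 0.01 * mu.lopt;
  if (lf < floor_lf) lf = floor_lf;
  double vf = -mu.r * omega / mu.cosa;
  double ln = lf / mu.lopt;
  double vn = vf / (10.0 * mu.lopt);
  double f = mu.fmax * (a * active_fl(ln) * force_vel(vn) + passive_fl(ln)) *
             mu.cosa;
  return f > 0.0 ? f : 0.0;
}

struct DerivWork {
  const std::vector<MusclePar>* mus;
  double I, mgd;
};

// State y = (theta, omega, a_1..a_nm); u = excitations at this time.
static void deriv(const DerivWork& wk, const double* y, const double* u,
                  double* dy) {
  const std::vector<MusclePar>& mus = *wk.mus;
  int nm = (int)mus.size();
  double theta = y[0], omega = y[1];
  double torque = 0.0;
  for (int m = 0; m < nm; ++m) {
    double f = muscle_force1(mus[m], theta, omega, y[2 + m]);
    torque += mus[m].r * f;
  }
  torque -= wk.mgd * std::sin(theta);
  dy[0] = omega;
  dy[1] = torque / wk.I;
  for (int m = 0; m < nm; ++m) {
    double um = u[m], am = y[2 + m];
    double tau = (um > am) ? mus[m].tact : mus[m].tdeact;
    dy[2 + m] = (um - am) / tau;
  }
}

// Fixed-step RK4 over nstep steps of size dt.  uhalf has 2*nstep + 1 rows
// (excitations on the half-step grid) and nm columns.  Fills theta, omega
// (length nstep + 1) and act (column-major (nstep+1) x nm).  Returns -1 on
// success or the index of the first non-finite step.
static int integrate_rk4(const std::vector<MusclePar>& mus, double I,
                         double mgd, const NumericMatrix& uhalf, double dt,
                         int nstep, double theta0, double omega0,
                         const NumericVector& a0, std::vector<double>& theta,
                         std::vector<double>& omega,
                         std::vector<double>& act) {
  int nm = (int)mus.size();
  int ns = 2 + nm;
  DerivWork wk;
  wk.mus = &mus;
  wk.I = I;
  wk.mgd = mgd;
  std::vector<double> y(ns), yt(ns), k1(ns), k2(ns), k3(ns), k4(ns),
      u0(nm), um(nm), u1(nm);
  y[0] = theta0;
  y[1] = omega0;
  for (int m = 0; m < nm; ++m) y[2 + m] = a0[m];
  theta[0] = y[0];
  omega[0] = y[1];
  for (int m = 0; m < nm; ++m) act[m * (nstep + 1)] = y[2 + m];
  for (int i = 0; i < nstep; ++i) {
    for (int m = 0; m < nm; ++m) {
      u0[m] = uhalf(2 * i, m);
      um[m] = uhalf(2 * i + 1, m);
      u1[m] = uhalf(2 * i + 2, m);
    }
    deriv(wk, y.data(), u0.data(), k1.data());
    for (int s = 0; s < ns; ++s) yt[s] = y[s] + 0.5 * dt * k1[s];
    deriv(wk, yt.data(), um.data(), k2.data());
    for (int s = 0; s < ns; ++s) yt[s] = y[s] + 0.5 * dt * k2[s];
    deriv(wk, yt.data(), um.data(), k3.data());
    for (int s = 0; s < ns; ++s) yt[s] = y[s] + dt * k3[s];
    deriv(wk, yt.data(), u1.data(), k4.data());
    for (int s = 0; s < ns; ++s)
      y[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
    // activations are a first-order lag between bounded signals; clamp the
    // integrator's tiny overshoots so a stays a valid activation
    for (int m = 0; m < nm; ++m) {
      if (y[2 + m] < 0.0) y[2 + m] = 0.0;
      if (y[2 + m] > 1.0) y[2 + m] = 1.0;
    }
    if (!std::isfinite(y[0]) || !std::isfinite(y[1]) ||
        std::fabs(y[0]) > 100.0)
      return i + 1;
    theta[i + 1] = y[0];
    omega[i + 1] = y[1];
    for (int m = 0; m < nm; ++m) act[m * (nstep + 1) + i + 1] = y[2 + m];
  }
  return -1;
}

// Forward simulation driven by excitations on the half-step grid.
// [[Rcpp::export]]
List cpp_forward(NumericMatrix uhalf, NumericMatrix muscle_par, double I,
                 double mgd, double dt, int nstep, double theta0,
                 double omega0, NumericVector a0) {
  std::vector<MusclePar> mus = parse_muscles(muscle_par);
  int nm = (int)mus.size();
  if (uhalf.nrow() != 2 * nstep + 1)
    stop("uhalf must have 2*nstep + 1 rows");
  if (uhalf.ncol() != nm) stop("uhalf must have one column per muscle");
  if (a0.size() != nm) stop("a0 must have one entry per muscle");
  std::vector<double> theta(nstep + 1), omega(nstep + 1),
      act((nstep + 1) * nm);
  int fail = integrate_rk4(mus, I, mgd, uhalf, dt, nstep, theta0, omega0, a0,
                           theta, omega, act);
  int nout = (fail < 0) ? nstep + 1 : fail;
  NumericVector th(nout), om(nout), tt(nout);
  NumericMatrix am(nout, nm), fm(nout, nm);
  for (int i = 0; i < nout; ++i) {
    tt[i] = i * dt;
    th[i] = theta[i];
    om[i] = omega[i];
    for (int m = 0; m < nm; ++m) {
      double a = act[m * (nstep + 1) + i];
      am(i, m) = a;
      fm(i, m) = muscle_force1(mus[m], theta[i], omega[i], a);
    }
  }
  return List::create(_["t"] = tt, _["theta"] = th, _["omega"] = om,
                      _["activations"] = am, _["forces"] = fm,
                      _["diverged"] = (fail >= 0),
                      _["fail_time"] = (fail >= 0) ? fail * dt : NA_REAL);
}

// Effort integral: sum over muscles of the trapezoid-rule integral of u^3
// on a uniform grid with spacing dt.
static double effort_trapz(const NumericMatrix& u, double dt) {
  int nt = u.nrow(), nm = u.ncol();
  double e = 0.0;
  for (int m = 0; m < nm; ++m) {
    double s = 0.0;
    for (int k = 0; k < nt; ++k) {
      double c = u(k, m);
      double w = (k == 0 || k == nt - 1) ? 0.5 : 1.0;
      s += w * c * c * c;
    }
    e += s * dt;
  }
  return e;
}

// [[Rcpp::export]]
double cpp_effort(NumericMatrix A, NumericVector centers, double w,
                  NumericVector t_lik) {
  NumericMatrix u = cpp_excitations(A, centers, w, t_lik);
  double dt = t_lik[1] - t_lik[0];
  return effort_trapz(u, dt);
}

// ---------------------------------------------------------------------------
// Fast log-posterior for the elbow problem:
//   amplitudes -> excitations -> forward dynamics -> tracking likelihood
//   + effort prior.  This is the sampler's hot path.
//
// lik_idx are 0-based indices into the integrator grid (0..nstep) picking
// out the likelihood/observation grid.
// ---------------------------------------------------------------------------
// Bhalf is the precomputed CRBF design matrix on the half-step grid
// ((2*nstep + 1) x n_nodes); centers and width are fixed per basis, so the
// per-proposal excitation reduces to a small matrix product.
// [[Rcpp::export]]
List cpp_elbow_logpost(NumericMatrix A, NumericMatrix Bhalf,
                       NumericMatrix muscle_par, double I, double mgd,
                       double dt, int nstep, double theta0, double omega0,
                       NumericVector a0, IntegerVector lik_idx,
                       NumericVector theta_ref, NumericVector omega_ref,
                       double sigma_pos, double sigma_vel, double sigma_eff,
                       double amp_bound, bool want_traj) {
  int nm = A.nrow(), nn = A.ncol();
  // bounds (uniform prior U(A)): reject before any simulation work
  for (int m = 0; m < nm; ++m)
    for (int i = 0; i < nn; ++i)
      if (!(std::fabs(A(m, i)) <= amp_bound))
        return List::create(_["lp"] = R_NegInf, _["loglik"] = R_NegInf,
                            _["logprior"] = R_NegInf, _["effort"] = NA_REAL,
                            _["diverged"] = false, _["in_bounds"] = false,
                            _["simulated"] = false);
  int nhalf = 2 * nstep + 1;
  if (Bhalf.nrow() != nhalf || Bhalf.ncol() != nn)
    stop("Bhalf must be (2*nstep + 1) x n_nodes");
  NumericMatrix uhalf(nhalf, nm);
  for (int m = 0; m < nm; ++m) {
    for (int k = 0; k < nhalf; ++k) {
      double f = 0.0;
      for (int i = 0; i < nn; ++i) f += A(m, i) * Bhalf(k, i);
      uhalf(k, m) = invlogit1(f);
    }
  }
  std::vector<MusclePar> mus = parse_muscles(muscle_par);
  std::vector<double> theta(nstep + 1), omega(nstep + 1),
      act((nstep + 1) * nm);
  int fail = integrate_rk4(mus, I, mgd, uhalf, dt, nstep, theta0, omega0, a0,
                           theta, omega, act);
  if (fail >= 0)
    return List::create(_["lp"] = R_NegInf, _["loglik"] = R_NegInf,
                        _["logprior"] = NA_REAL, _["effort"] = NA_REAL,
                        _["diverged"] = true, _["in_bounds"] = true,
                        _["simulated"] = true);
  int nl = lik_idx.size();
  if (theta_ref.size() != nl || omega_ref.size() != nl)
    stop("reference series must match the likelihood grid");
  double ll = 0.0;
  for (int k = 0; k < nl; ++k) {
    int j = lik_idx[k];
    double ep = (theta_ref[k] - theta[j]) / sigma_pos;
    double ev = (omega_ref[k] - omega[j]) / sigma_vel;
    ll += ep * ep + ev * ev;
  }
  ll *= -0.5;
  // excitations on the likelihood grid for the effort prior
  NumericMatrix ulik(nl, nm);
  for (int k = 0; k < nl; ++k)
    for (int m = 0; m < nm; ++m) ulik(k, m) = uhalf(2 * lik_idx[k], m);
  double dtl = (lik_idx[1] - lik_idx[0]) * dt;
  double eff = effort_trapz(ulik, dtl);
  double zp = eff / sigma_eff;
  double lprior = -0.5 * zp * zp;
  List out = List::create(_["lp"] = ll + lprior, _["loglik"] = ll,
                          _["logprior"] = lprior, _["effort"] = eff,
                          _["diverged"] = false, _["in_bounds"] = true,
                          _["simulated"] = true);
  if (want_traj) {
    NumericVector thl(nl), oml(nl);
    NumericMatrix fml(nl, nm);
    for (int k = 0; k < nl; ++k) {
      int j = lik_idx[k];
      thl[k] = theta[j];
      oml[k] = omega[j];
      for (int m = 0; m < nm; ++m)
        fml(k, m) =
            muscle_force1(mus[m], theta[j], omega[j], act[m * (nstep + 1) + j]);
    }
    out["theta_lik"] = thl;
    out["omega_lik"] = oml;
    out["forces_lik"] = fml;
    out["u_lik"] = ulik;
  }
  return out;
}
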