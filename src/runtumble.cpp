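// Inner loops of the run-and-tumble toolkit: Euler-Maruyama Langevin engines
// in (f, s) and (r, v) coordinates, the event-level agent simulator, and the
// explicit finite-volume stepper of the angular-moment Fokker-Planck system.
// All randomness comes from R's RNG (RNGScope), so set.seed() on the R side
// fully determines every trajectory.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double f) { return 1.0 / (1.0 + std::exp(-f)); }

// tau_D(f)/t_M given the adapted value and the diffusion ratio dtr = D_T/D_R
static inline double tau_d_of(double r, double r0, double tau_d0, double dtr) {
  return tau_d0 * (r0 + (1.0 - r0) * dtr) / (r + (1.0 - r) * dtr);
}

// reflect s into [-1, 1] (Euler steps can overshoot where the noise vanishes)
static inline double reflect_s(double s) {
  while (s > 1.0 || s < -1.0) {
    if (s > 1.0) s = 2.0 - s;
    if (s < -1.0) s = -2.0 - s;
  }
  return s;
}

// [[Rcpp::export]]
List langevin_fs_cpp(int n_walkers, double dt, int n_steps, int save_every,
                     double inv_tau_e, double tau_d0, double r0, double f0,
                     int n, double dtr, double sigma_f,
                     bool keep_x, bool keep_f, bool keep_s) {
  RNGScope scope;
  const int n_save = n_steps / save_every;
  NumericMatrix xm(keep_x ? n_save : 0, keep_x ? n_walkers : 0);
  NumericMatrix fm(keep_f ? n_save : 0, keep_f ? n_walkers : 0);
  NumericMatrix sm(keep_s ? n_save : 0, keep_s ? n_walkers : 0);
  NumericVector times(n_save);
  std::vector<double> f(n_walkers, f0), s(n_walkers), x(n_walkers, 0.0);
  const double ang = 2.0 / (double)(n - 1);
  for (int w = 0; w < n_walkers; ++w) {
    // isotropic start: uniform in s for n = 3, cos(uniform angle) for n = 2
    s[w] = (n == 3) ? R::runif(-1.0, 1.0) : std::cos(R::runif(0.0, M_PI));
  }
  const double sqdt = std::sqrt(dt);
  int row = 0;
  for (int it = 1; it <= n_steps; ++it) {
    for (int w = 0; w < n_walkers; ++w) {
      const double fw = f[w], sw = s[w];
      const double r = logistic(fw);
      const double td = tau_d_of(r, r0, tau_d0, dtr);
      x[w] += r * sw * dt;
      double fn = fw + (-(fw - f0) + r * sw * inv_tau_e) * dt;
      if (sigma_f > 0.0) fn += sigma_f * sqdt * R::norm_rand();
      double amp2 = ang * (1.0 - sw * sw) / td;
      if (amp2 < 0.0) amp2 = 0.0;
      double sn = sw - sw / td * dt + std::sqrt(amp2 * dt) * R::norm_rand();
      s[w] = reflect_s(sn);
      f[w] = fn;
    }
    if (it % save_every == 0) {
      times[row] = it * dt;
      for (int w = 0; w < n_walkers; ++w) {
        if (keep_x) xm(row, w) = x[w];
        if (keep_f) fm(row, w) = f[w];
        if (keep_s) sm(row, w) = s[w];
      }
      ++row;
    }
  }
  return List::create(_["times"] = times, _["x"] = xm, _["f"] = fm,
                      _["s"] = sm);
}

// [[Rcpp::export]]
List langevin_rv_cpp(int n_walkers, double dt, int n_steps, int save_every,
                     double inv_tau_e, double tau_d0, double r0, double f0,
                     int n, double dtr, double r_start, double v_start,
                     bool random_init, double noise_scale,
                     bool keep_x, bool keep_r, bool keep_v) {
  RNGScope scope;
  const int n_save = n_steps / save_every;
  NumericMatrix xm(keep_x ? n_save : 0, keep_x ? n_walkers : 0);
  NumericMatrix rm(keep_r ? n_save : 0, keep_r ? n_walkers : 0);
  NumericMatrix vm(keep_v ? n_save : 0, keep_v ? n_walkers : 0);
  NumericVector times(n_save);
  std::vector<double> r(n_walkers), v(n_walkers), x(n_walkers, 0.0);
  const double eps = 1e-6;
  const double ang = 2.0 / (double)(n - 1);
  for (int w = 0; w < n_walkers; ++w) {
    if (random_init) {
      double s0 = (n == 3) ? R::runif(-1.0, 1.0) : std::cos(R::runif(0.0, M_PI));
      r[w] = r0;
      v[w] = r0 * s0;
    } else {
      r[w] = r_start;
      v[w] = v_start;
    }
  }
  const double sqdt = std::sqrt(dt);
  int row = 0;
  for (int it = 1; it <= n_steps; ++it) {
    for (int w = 0; w < n_walkers; ++w) {
      double rw = r[w], vw = v[w];
      const double fr = std::log(rw / (1.0 - rw));
      const double drive = -(fr - f0) + vw * inv_tau_e;
      const double td = tau_d_of(rw, r0, tau_d0, dtr);
      x[w] += vw * dt;
      double rn = rw + rw * (1.0 - rw) * drive * dt;
      double amp2 = ang * (rw * rw - vw * vw) / td;
      if (amp2 < 0.0) amp2 = 0.0;
      double vn = vw + (vw * (1.0 - rw) * drive - vw / td) * dt +
                  noise_scale * std::sqrt(amp2 * dt) * R::norm_rand();
      if (rn < eps) rn = eps;
      if (rn > 1.0 - eps) rn = 1.0 - eps;
      if (vn > rn) vn = rn;          // |v| <= r by projection
      if (vn < -rn) vn = -rn;
      r[w] = rn;
      v[w] = vn;
    }
    if (it % save_every == 0) {
      times[row] = it * dt;
      for (int w = 0; w < n_walkers; ++w) {
        if (keep_x) xm(row, w) = x[w];
        if (keep_r) rm(row, w) = r[w];
        if (keep_v) vm(row, w) = v[w];
      }
      ++row;
    }
  }
  return List::create(_["times"] = times, _["x"] = xm, _["r"] = rm,
                      _["v"] = vm);
}

// --- gradient profiles (agent engine) --------------------------------------
// kind: 0 exponential (p1 = C0, p2 = L0), 1 linear (C1, a1),
//       2 localized source (C2, R0), 3 tabulated phi(R) (linear interp)
struct Profile {
  int kind;
  double p1, p2, Ki, Ka;
  bool saturating;
  const double *Rt, *Pt;  // tabulated phi for kind 3
  int nt;
  double conc(double R) const {
    switch (kind) {
      // planar exponential is an unbounded ramp (R may be negative); the
      // planar linear profile is a symmetric ridge about the source plane
      case 0: return p1 * std::exp(-R / p2);
      case 1: { double c = p1 - p2 * std::fabs(R); return c > 0.0 ? c : 0.0; }
      case 2: return (R <= p2) ? p1 : p1 * p2 / R;
      default: return 0.0;
    }
  }
  double phi(double R) const {
    if (kind == 3) {  // tabulated phi(R), clamped linear interpolation
      if (R <= Rt[0]) return Pt[0];
      if (R >= Rt[nt - 1]) return Pt[nt - 1];
      int lo = 0, hi = nt - 1;
      while (hi - lo > 1) { int mid = (lo + hi) / 2; (Rt[mid] <= R ? lo : hi) = mid; }
      double t = (R - Rt[lo]) / (Rt[lo + 1] - Rt[lo]);
      return Pt[lo] + t * (Pt[lo + 1] - Pt[lo]);
    }
    const double C = conc(R);
    if (saturating) return std::log1p(C / Ki) - std::log1p(C / Ka);
    return (C > 1e-300) ? std::log(C) : -690.0;  // flat floor: no gradient
  }
};

// rotate unit 3-vector u by angle alpha about a uniformly random axis
// perpendicular to u
static inline void rotate3(double *u, double alpha) {
  double g0 = R::norm_rand(), g1 = R::norm_rand(), g2 = R::norm_rand();
  double dot = g0 * u[0] + g1 * u[1] + g2 * u[2];
  double p0 = g0 - dot * u[0], p1 = g1 - dot * u[1], p2 = g2 - dot * u[2];
  double nrm = std::sqrt(p0 * p0 + p1 * p1 + p2 * p2);
  if (nrm < 1e-12) return;  // measure-zero; skip this rotation
  p0 /= nrm; p1 /= nrm; p2 /= nrm;
  const double ca = std::cos(alpha), sa = std::sin(alpha);
  u[0] = ca * u[0] + sa * p0;
  u[1] = ca * u[1] + sa * p1;
  u[2] = ca * u[2] + sa * p2;
  nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

// [[Rcpp::export]]
List agent_sim_cpp(int n_walkers, double dt, int n_steps, int save_every,
                   int n, double v0, double t_m, double Ngain, double H,
                   double F0, double d_r, double d_t, double t_s,
                   double sigma_f, int kind, double p1, double p2,
                   double Ki, double Ka, bool saturating, bool radial,
                   double R_start, NumericVector R_tab, NumericVector phi_tab) {
  RNGScope scope;
  Profile prof{kind, p1, p2, Ki, Ka, saturating,
               R_tab.begin(), phi_tab.begin(), (int)R_tab.size()};
  const int n_save = n_steps / save_every;
  NumericMatrix Rm(n_save, n_walkers), fm(n_save, n_walkers),
      sm(n_save, n_walkers);
  IntegerMatrix statem(n_save, n_walkers);
  NumericVector times(n_save);
  const double r0 = logistic(H * F0);
  // state arrays: position (3 components; planar uses only [0]), direction,
  // internal state F, motility
  std::vector<double> X(3 * n_walkers, 0.0), U(3 * n_walkers, 0.0),
      Fst(n_walkers, F0), phiv(n_walkers);
  std::vector<int> run(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    X[3 * w] = R_start;
    double *u = &U[3 * w];
    if (n == 3) {
      double z = R::runif(-1.0, 1.0), ph = R::runif(0.0, 2.0 * M_PI);
      double rr = std::sqrt(1.0 - z * z);
      u[0] = rr * std::cos(ph); u[1] = rr * std::sin(ph); u[2] = z;
    } else {
      double th = R::runif(0.0, 2.0 * M_PI);
      u[0] = std::cos(th); u[1] = std::sin(th); u[2] = 0.0;
    }
    run[w] = (R::unif_rand() < r0) ? 1 : 0;
    phiv[w] = prof.phi(R_start);
  }
  const double sq_f = std::sqrt(dt / t_m);
  int row = 0;
  for (int it = 1; it <= n_steps; ++it) {
    for (int w = 0; w < n_walkers; ++w) {
      double *x = &X[3 * w];
      double *u = &U[3 * w];
      double dphi = 0.0;
      const double D = run[w] ? d_r : d_t;
      if (run[w]) {
        x[0] += v0 * u[0] * dt;
        if (radial) { x[1] += v0 * u[1] * dt; x[2] += v0 * u[2] * dt; }
        double R = radial
            ? std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2])
            : x[0];
        double ph = prof.phi(R);
        dphi = ph - phiv[w];
        phiv[w] = ph;
      }
      // reorientation: runs and tumbles differ only in D
      if (n == 3) {
        rotate3(u, std::sqrt(4.0 * D * dt) * R::norm_rand());
      } else {
        double th = std::atan2(u[1], u[0]) +
                    std::sqrt(2.0 * D * dt) * R::norm_rand();
        u[0] = std::cos(th); u[1] = std::sin(th);
      }
      // internal state: linear relaxation + receptor drive (Eq of motion of F)
      double Fw = Fst[w];
      Fw += -(Fw - F0) / t_m * dt + Ngain * dphi;
      if (sigma_f > 0.0) Fw += sigma_f / H * sq_f * R::norm_rand();
      Fst[w] = Fw;
      // Poisson switching with rates lambda_R = (1-r)/t_S, lambda_T = r/t_S
      const double r = logistic(H * Fw);
      if (run[w]) {
        if (R::unif_rand() < -std::expm1(-(1.0 - r) / t_s * dt)) run[w] = 0;
      } else {
        if (R::unif_rand() < -std::expm1(-r / t_s * dt)) run[w] = 1;
      }
    }
    if (it % save_every == 0) {
      times[row] = it * dt;
      for (int w = 0; w < n_walkers; ++w) {
        double *x = &X[3 * w];
        double *u = &U[3 * w];
        double R, s_up;
        if (radial) {
          R = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
          // uphill = toward the source at the origin (C decreases with R)
          s_up = (R > 1e-12)
              ? -(u[0] * x[0] + u[1] * x[1] + u[2] * x[2]) / R
              : 0.0;
        } else {
          R = x[0];
          // uphill is toward the source plane; the linear ridge is symmetric
          s_up = (kind == 1 && x[0] < 0.0) ? u[0] : -u[0];
        }
        Rm(row, w) = R;
        fm(row, w) = H * Fst[w];
        sm(row, w) = s_up;
        statem(row, w) = run[w];
      }
      ++row;
    }
  }
  return List::create(_["times"] = times, _["R"] = Rm, _["f"] = fm,
                      _["s"] = sm, _["state"] = statem);
}

// --- angular-moment Fokker-Planck stepper -----------------------------------
// State m: G x (K+1) matrix of orthonormal-Gegenbauer coefficients on a
// uniform f grid. Flux F_k = u1(f) m_k + u2(f) (S m)_k with S the symmetric
// tridiagonal coupling. Roe-type upwind: A(f) = u1 I + u2 S has the
// f-independent eigenvectors of S, so |A| = V diag(|u1 + u2 lam_j|) V^T.
// Damping lam_k (k-th angular eigenvalue) acts pointwise.
// [[Rcpp::export]]
List fp_solve_cpp(NumericMatrix m0, NumericVector f_grid, double f0,
                  double inv_tau_e, NumericVector inv_tau_d,  // at cell centers
                  NumericVector r_half,                       // at interfaces
                  NumericVector lam,                          // angular eigvals
                  NumericVector sdiag,       // coupling super/sub diagonal, K
                  NumericMatrix V, NumericVector lamS,  // eigen of S
                  int n, double dt, int n_steps, int check_every,
                  double rtol_stop) {
  const int G = m0.nrow(), Kp1 = m0.ncol(), K = Kp1 - 1;
  const int Gi = G - 1;  // interior interfaces, between cells i and i+1
  const double df = f_grid[1] - f_grid[0];
  std::vector<double> m(m0.begin(), m0.end());       // column-major G*(K+1)
  std::vector<double> Sm(G * Kp1), flux(G * Kp1, 0.0), dj(Gi * Kp1),
      aw(Gi * Kp1), dampc(G * Kp1), u1h(Gi), u2h(Gi), Vt(Kp1 * Kp1);
  const double invn1 = 1.0 / (double)(n - 1);
  // all mode-major layouts are contiguous in the grid index so the inner
  // loops vectorize; flux[k*Gi + i] is the flux through the interface
  // between cells i and i+1 (domain-end fluxes are zero and kept implicit)
  for (int i = 0; i < Gi; ++i) {
    u1h[i] = -(0.5 * (f_grid[i] + f_grid[i + 1]) - f0);
    u2h[i] = r_half[i + 1] * inv_tau_e;
  }
  for (int k = 0; k <= K; ++k) {
    for (int j = 0; j <= K; ++j) Vt[k * Kp1 + j] = V(k, j);
    for (int i = 0; i < G; ++i) {
      dampc[k * G + i] = lam[k] * invn1 * inv_tau_d[i];  // lam <= 0
    }
  }
  std::vector<double> res_v, res_t;
  double res = NA_REAL;
  int it = 0;
  for (it = 1; it <= n_steps; ++it) {
    // S m (tridiagonal in k) and jumps across interfaces
    for (int k = 0; k <= K; ++k) {
      const double cl = (k > 0) ? sdiag[k - 1] : 0.0;
      const double cu = (k < K) ? sdiag[k] : 0.0;
      double *out = &Sm[k * G];
      const double *ml = (k > 0) ? &m[(k - 1) * G] : nullptr;
      const double *mu = (k < K) ? &m[(k + 1) * G] : nullptr;
      if (ml && mu) {
        for (int i = 0; i < G; ++i) out[i] = cl * ml[i] + cu * mu[i];
      } else if (mu) {
        for (int i = 0; i < G; ++i) out[i] = cu * mu[i];
      } else {
        for (int i = 0; i < G; ++i) out[i] = cl * ml[i];
      }
      const double *mk = &m[k * G];
      double *dk = &dj[k * Gi];
      for (int i = 0; i < Gi; ++i) dk[i] = mk[i + 1] - mk[i];
    }
    // central part of the flux
    for (int k = 0; k <= K; ++k) {
      const double *mk = &m[k * G], *sk = &Sm[k * G];
      double *fk = &flux[k * Gi];
      for (int i = 0; i < Gi; ++i) {
        fk[i] = 0.5 * (u1h[i] * (mk[i] + mk[i + 1]) +
                       u2h[i] * (sk[i] + sk[i + 1]));
      }
    }
    // characteristic upwind correction: flux -= 0.5 V |u1 + u2 lamS| V^T d
    for (int j = 0; j <= K; ++j) {
      double *ajv = &aw[j * Gi];
      std::fill(ajv, ajv + Gi, 0.0);
      for (int k = 0; k <= K; ++k) {
        const double vkj = Vt[k * Kp1 + j];
        if (vkj == 0.0) continue;
        const double *dk = &dj[k * Gi];
        for (int i = 0; i < Gi; ++i) ajv[i] += vkj * dk[i];
      }
      const double lj = lamS[j];
      for (int i = 0; i < Gi; ++i) ajv[i] *= std::fabs(u1h[i] + u2h[i] * lj);
    }
    for (int k = 0; k <= K; ++k) {
      double *fk = &flux[k * Gi];
      for (int j = 0; j <= K; ++j) {
        const double vkj = Vt[k * Kp1 + j];
        if (vkj == 0.0) continue;
        const double *ajv = &aw[j * Gi];
        for (int i = 0; i < Gi; ++i) fk[i] -= 0.5 * vkj * ajv[i];
      }
    }
    // conservative update with zero flux at the domain ends
    double dnorm = 0.0, mnorm = 0.0;
    const bool check = (it % check_every == 0) || (it == n_steps);
    for (int k = 0; k <= K; ++k) {
      double *mk = &m[k * G];
      const double *fk = &flux[k * Gi];
      const double *dc = &dampc[k * G];
      for (int i = 0; i < G; ++i) {
        const double fl = (i > 0) ? fk[i - 1] : 0.0;
        const double fr = (i < Gi) ? fk[i] : 0.0;
        double upd = (fl - fr) / df + dc[i] * mk[i];
        double mn = mk[i] + dt * upd;
        // flush tiny magnitudes: subnormals in the far tails otherwise
        // dominate the runtime on x86
        mk[i] = (std::fabs(mn) < 1e-280) ? 0.0 : mn;
        if (check) { dnorm += upd * upd; mnorm += mk[i] * mk[i]; }
      }
    }
    if (check) {
      res = std::sqrt(dnorm / (mnorm + 1e-300));  // per unit tau
      res_v.push_back(res);
      res_t.push_back(it * dt);
      if (res < rtol_stop) break;
    }
  }
  NumericMatrix mout(G, Kp1);
  std::copy(m.begin(), m.end(), mout.begin());
  return List::create(_["m"] = mout, _["residual"] = res,
                      _["res_history"] = wrap(res_v),
                      _["res_tau"] = wrap(res_t),
                      _["steps"] = std::min(it, n_steps));
}
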