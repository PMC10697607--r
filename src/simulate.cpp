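// Compiled core of the self-propelled rigid-body integrator.
//
// Reference state layout (length 12): X(3) global position, V(3) global
// velocity, (psi, theta, phi) Euler angles, omega(3) body-frame angular
// velocity. The force model mirrors the R reference implementations in
// forces.R; tests assert agreement to near machine precision.
//
// The integrator itself evolves the rotation matrix directly (an 18-state
// formulation with dR/dt = -[omega]x R and per-step re-orthonormalization)
// instead of Euler angles: turns about oblique axes sweep the pitch through
// +-90 degrees, where the Euler-angle kinematics are singular. Euler angles
// are extracted from R only for output samples.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  int n;                       // number of ctenes
  std::vector<double> dx, dy, dz;   // plate sliding direction, body frame
  std::vector<double> rx, ry, rz;   // ctene position, body frame
  std::vector<double> f, offset, t_p, t_r;
  double direction;
  double a_x, c_y, a_y;        // tip-path ellipse geometry
  double rho, nu, w_plate;
  double C_inf, alpha_A;       // plate drag
  double Re_lo, Re_hi;         // validity clamp
  double L_B, area_par, area_perp, K_par, K_perp, c1, c2;   // body drag
  double m, rhoV, Cm_par, Cm_perp;                          // inertia terms
  double r_e, G_par, G_perp, c3, c4;                        // opposing torque
  double I1, I2;               // moments of inertia (I2 = I3)
};

static Params unpack(const List& p) {
  Params q;
  NumericMatrix d = p["d_body"], r = p["r_body"];
  NumericVector f = p["f"], off = p["offset"], tp = p["t_p"], tr = p["t_r"];
  q.n = d.nrow();
  q.dx.resize(q.n); q.dy.resize(q.n); q.dz.resize(q.n);
  q.rx.resize(q.n); q.ry.resize(q.n); q.rz.resize(q.n);
  q.f.resize(q.n); q.offset.resize(q.n); q.t_p.resize(q.n); q.t_r.resize(q.n);
  for (int i = 0; i < q.n; ++i) {
    q.dx[i] = d(i, 0); q.dy[i] = d(i, 1); q.dz[i] = d(i, 2);
    q.rx[i] = r(i, 0); q.ry[i] = r(i, 1); q.rz[i] = r(i, 2);
    q.f[i] = f[i]; q.offset[i] = off[i]; q.t_p[i] = tp[i]; q.t_r[i] = tr[i];
  }
  q.direction = as<double>(p["direction"]);
  q.a_x = as<double>(p["a_x"]); q.c_y = as<double>(p["c_y"]);
  q.a_y = as<double>(p["a_y"]);
  q.rho = as<double>(p["rho"]); q.nu = as<double>(p["nu"]);
  q.w_plate = as<double>(p["w_plate"]);
  q.C_inf = as<double>(p["C_inf"]); q.alpha_A = as<double>(p["alpha_A"]);
  q.Re_lo = as<double>(p["Re_lo"]); q.Re_hi = as<double>(p["Re_hi"]);
  q.L_B = as<double>(p["L_B"]);
  q.area_par = as<double>(p["area_par"]); q.area_perp = as<double>(p["area_perp"]);
  q.K_par = as<double>(p["K_par"]); q.K_perp = as<double>(p["K_perp"]);
  q.c1 = as<double>(p["c1"]); q.c2 = as<double>(p["c2"]);
  q.m = as<double>(p["m"]); q.rhoV = as<double>(p["rhoV"]);
  q.Cm_par = as<double>(p["Cm_par"]); q.Cm_perp = as<double>(p["Cm_perp"]);
  q.r_e = as<double>(p["r_e"]);
  q.G_par = as<double>(p["G_par"]); q.G_perp = as<double>(p["G_perp"]);
  q.c3 = as<double>(p["c3"]); q.c4 = as<double>(p["c4"]);
  q.I1 = as<double>(p["I1"]); q.I2 = as<double>(p["I2"]);
  return q;
}

// periodic remainder in [0, T); avoids std::fmod so the object only needs
// baseline libm symbols
static inline double pmod(double x, double T) {
  double r = x - std::floor(x / T) * T;
  if (r >= T) r -= T;
  if (r < 0) r += T;
  return r;
}

static inline double clampRe(double Re, const Params& q) {
  if (Re < q.Re_lo) return q.Re_lo;
  if (Re > q.Re_hi) return q.Re_hi;
  return Re;
}

// global-to-body rotation matrix, row-major R[3][3]
static void rotmat(double psi, double theta, double phi, double R[3][3]) {
  double cps = std::cos(psi), sps = std::sin(psi);
  double cth = std::cos(theta), sth = std::sin(theta);
  double cph = std::cos(phi), sph = std::sin(phi);
  R[0][0] = cth * cps;                 R[0][1] = cth * sps;                 R[0][2] = -sth;
  R[1][0] = sph * sth * cps - cph * sps; R[1][1] = sph * sth * sps + cph * cps; R[1][2] = sph * cth;
  R[2][0] = cph * sth * cps + sph * sps; R[2][1] = cph * sth * sps - sph * cps; R[2][2] = cph * cth;
}

// tip oscillatory speed and instantaneous plate length of ctene i at time t
static inline void tip(const Params& q, int i, double t,
                       double& xdot, double& yA) {
  double f = q.f[i];
  if (f <= 0.0) { xdot = 0.0; yA = q.c_y; return; }
  double T = 1.0 / f;
  double s = pmod(t - q.offset[i], T);
  if (q.direction < 0) { s = T - s; if (s >= T) s -= T; }
  double eta, rate;
  if (s < q.t_p[i]) { eta = M_PI * s / q.t_p[i]; rate = M_PI / q.t_p[i]; }
  else { eta = M_PI + M_PI * (s - q.t_p[i]) / q.t_r[i]; rate = M_PI / q.t_r[i]; }
  if (q.direction < 0) rate = -rate;
  xdot = -q.a_x * std::sin(eta) * rate;
  yA = q.c_y + q.a_y * std::sin(eta);
}

// translational acceleration and body-frame angular acceleration given the
// rotation matrix, velocity and angular velocity
static void core_accels(const Params& q, double t, const double R[3][3],
                        const double* V, const double* w,
                        double* acc, double* wdot) {
  // propulsive force (global) and torque (body)
  double F[3] = {0, 0, 0}, tau[3] = {0, 0, 0};
  for (int i = 0; i < q.n; ++i) {
    double xdot, yA;
    tip(q, i, t, xdot, yA);
    double sp = std::fabs(xdot);
    if (sp <= 0.0) continue;
    // u = R^T (xdot * d'), global frame
    double u0 = xdot * (R[0][0] * q.dx[i] + R[1][0] * q.dy[i] + R[2][0] * q.dz[i]);
    double u1 = xdot * (R[0][1] * q.dx[i] + R[1][1] * q.dy[i] + R[2][1] * q.dz[i]);
    double u2 = xdot * (R[0][2] * q.dx[i] + R[1][2] * q.dy[i] + R[2][2] * q.dz[i]);
    double r0 = V[0] + u0, r1 = V[1] + u1, r2 = V[2] + u2;
    double rel2 = r0 * r0 + r1 * r1 + r2 * r2;
    double Re_p = clampRe(sp * yA / q.nu, q);
    double C_A = q.C_inf + q.alpha_A / std::sqrt(Re_p);
    double coef = -(q.rho * q.w_plate / 2.0) * yA * C_A * rel2 / sp;
    double f0 = coef * u0, f1 = coef * u1, f2 = coef * u2;
    F[0] += f0; F[1] += f1; F[2] += f2;
    // body-frame force for the torque
    double b0 = R[0][0] * f0 + R[0][1] * f1 + R[0][2] * f2;
    double b1 = R[1][0] * f0 + R[1][1] * f1 + R[1][2] * f2;
    double b2 = R[2][0] * f0 + R[2][1] * f1 + R[2][2] * f2;
    tau[0] += q.ry[i] * b2 - q.rz[i] * b1;
    tau[1] += q.rz[i] * b0 - q.rx[i] * b2;
    tau[2] += q.rx[i] * b1 - q.ry[i] * b0;
  }

  // body drag (global)
  double speed = std::sqrt(V[0] * V[0] + V[1] * V[1] + V[2] * V[2]);
  if (speed > 0.0) {
    double vb0 = R[0][0] * V[0] + R[0][1] * V[1] + R[0][2] * V[2];
    double vb1 = R[1][0] * V[0] + R[1][1] * V[1] + R[1][2] * V[2];
    double vb2 = R[2][0] * V[0] + R[2][1] * V[1] + R[2][2] * V[2];
    double Re_b = clampRe(speed * q.L_B / q.nu, q);
    double corr = 1.0 + q.c1 * std::pow(Re_b, q.c2);
    double Cpar = 24.0 / Re_b * q.K_par * corr;
    double Cperp = 24.0 / Re_b * q.K_perp * corr;
    double g0 = -(q.rho / 2.0) * q.area_par * Cpar * speed * vb0;
    double g1 = -(q.rho / 2.0) * q.area_perp * Cperp * speed * vb1;
    double g2 = -(q.rho / 2.0) * q.area_perp * Cperp * speed * vb2;
    F[0] += R[0][0] * g0 + R[1][0] * g1 + R[2][0] * g2;
    F[1] += R[0][1] * g0 + R[1][1] * g1 + R[2][1] * g2;
    F[2] += R[0][2] * g0 + R[1][2] * g1 + R[2][2] * g2;
  }

  // effective mass matrix M = m I3 + rhoV R^T diag(Cm) R
  double M[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = q.Cm_par * R[0][i] * R[0][j] +
                 q.Cm_perp * (R[1][i] * R[1][j] + R[2][i] * R[2][j]);
      M[i][j] = q.rhoV * s + (i == j ? q.m : 0.0);
    }
  // solve M acc = F (Cramer)
  double det =
    M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
    M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
    M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  double a0 =
    (F[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
     M[0][1] * (F[1] * M[2][2] - M[1][2] * F[2]) +
     M[0][2] * (F[1] * M[2][1] - M[1][1] * F[2])) / det;
  double a1 =
    (M[0][0] * (F[1] * M[2][2] - M[1][2] * F[2]) -
     F[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
     M[0][2] * (M[1][0] * F[2] - F[1] * M[2][0])) / det;
  double a2 =
    (M[0][0] * (M[1][1] * F[2] - F[1] * M[2][1]) -
     M[0][1] * (M[1][0] * F[2] - F[1] * M[2][0]) +
     F[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0])) / det;

  // opposing torque (body frame)
  double Top[3];
  double Gf[3] = {q.G_par, q.G_perp, q.G_perp};
  for (int i = 0; i < 3; ++i) {
    double wi = w[i];
    if (wi == 0.0) { Top[i] = 0.0; continue; }
    double Re_r = clampRe(std::fabs(wi) * q.r_e * q.r_e / q.nu, q);
    double C_R = 16.0 * M_PI / Re_r * Gf[i] * (1.0 + q.c3 * std::pow(Re_r, q.c4));
    Top[i] = -(q.rho / 2.0) * std::pow(q.r_e, 5) *
             (wi > 0 ? 1.0 : -1.0) * C_R * wi * wi;
  }
  // gyroscopic term omega x (I omega), I = diag(I1, I2, I2)
  double gy0 = 0.0;                            // (I3 - I2) w2 w3 = 0
  double gy1 = (q.I1 - q.I2) * w[2] * w[0];
  double gy2 = (q.I2 - q.I1) * w[0] * w[1];

  acc[0] = a0; acc[1] = a1; acc[2] = a2;
  wdot[0] = (tau[0] + Top[0] - gy0) / q.I1;
  wdot[1] = (tau[1] + Top[1] - gy1) / q.I2;
  wdot[2] = (tau[2] + Top[2] - gy2) / q.I2;
}

// time derivative of the 12-component Euler-angle state (reference form,
// used for cross-checks against the R force implementations)
static void deriv(const Params& q, double t, const double* y, double* dy) {
  const double* V = y + 3;
  double theta = y[7], phi = y[8];
  const double* w = y + 9;
  double R[3][3];
  rotmat(y[6], theta, phi, R);
  double acc[3], wdot[3];
  core_accels(q, t, R, V, w, acc, wdot);
  double cth = std::cos(theta);
  if (std::fabs(cth) <= 1e-6)
    stop("gimbal lock: |cos(theta)| <= 1e-6 during integration");
  double sph = std::sin(phi), cph = std::cos(phi);
  dy[0] = V[0]; dy[1] = V[1]; dy[2] = V[2];
  dy[3] = acc[0]; dy[4] = acc[1]; dy[5] = acc[2];
  dy[6] = (w[1] * sph + w[2] * cph) / cth;
  dy[7] = w[1] * cph - w[2] * sph;
  dy[8] = w[0] + (w[1] * sph + w[2] * cph) * std::tan(theta);
  dy[9] = wdot[0]; dy[10] = wdot[1]; dy[11] = wdot[2];
}

// time derivative of the 18-component DCM state:
// [X(3), V(3), R row-major (9), omega(3)]
static void deriv18(const Params& q, double t, const double* y, double* dy) {
  const double* V = y + 3;
  const double* w = y + 15;
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = y[6 + 3 * i + j];
  double acc[3], wdot[3];
  core_accels(q, t, R, V, w, acc, wdot);
  dy[0] = V[0]; dy[1] = V[1]; dy[2] = V[2];
  dy[3] = acc[0]; dy[4] = acc[1]; dy[5] = acc[2];
  // dR/dt = -[omega]x R
  for (int j = 0; j < 3; ++j) {
    dy[6 + j] = -(-w[2] * R[1][j] + w[1] * R[2][j]);
    dy[9 + j] = -(w[2] * R[0][j] - w[0] * R[2][j]);
    dy[12 + j] = -(-w[1] * R[0][j] + w[0] * R[1][j]);
  }
  dy[15] = wdot[0]; dy[16] = wdot[1]; dy[17] = wdot[2];
}

// re-orthonormalize the rotation block (modified Gram-Schmidt on rows)
static void renormalize(double* y) {
  double* R = y + 6;
  for (int i = 0; i < 3; ++i) {
    double* ri = R + 3 * i;
    for (int k = 0; k < i; ++k) {
      double* rk = R + 3 * k;
      double d = ri[0] * rk[0] + ri[1] * rk[1] + ri[2] * rk[2];
      ri[0] -= d * rk[0]; ri[1] -= d * rk[1]; ri[2] -= d * rk[2];
    }
    double n = std::sqrt(ri[0] * ri[0] + ri[1] * ri[1] + ri[2] * ri[2]);
    ri[0] /= n; ri[1] /= n; ri[2] /= n;
  }
}

static inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// [[Rcpp::export(name = ".cteno_deriv_cpp")]]
NumericVector cteno_deriv_cpp(double t, NumericVector state, List pars) {
  if (state.size() != 12) stop("state must have length 12");
  Params q = unpack(pars);
  NumericVector out(12);
  deriv(q, t, state.begin(), out.begin());
  return out;
}

// write one output row: t, X, V, Euler angles extracted from R, omega
static void write_sample(NumericMatrix& out, int row, double t,
                         const double* y) {
  out(row, 0) = t;
  for (int i = 0; i < 6; ++i) out(row, i + 1) = y[i];
  const double* R = y + 6;
  out(row, 7) = std::atan2(R[1], R[0]);            // psi
  out(row, 8) = std::asin(clamp1(-R[2]));          // theta
  out(row, 9) = std::atan2(R[5], R[8]);            // phi
  for (int i = 0; i < 3; ++i) out(row, i + 10) = y[15 + i];
}

// Fixed-step classical RK4 on the 18-component DCM state; returns samples
// every `stride` steps (rows: t, X, V, Euler angles, omega), always
// including the initial and final states, plus the exact final 18-state for
// chaining segments. Time is carried as an integer step count from `step0`
// so chained segments reproduce a single long run bit for bit.
// [[Rcpp::export(name = ".cteno_rk4_cpp")]]
List cteno_rk4_cpp(NumericVector state0, int step0, int nsteps,
                   double dt, int stride, List pars) {
  if (state0.size() != 12 && state0.size() != 18)
    stop("state must have length 12 (Euler) or 18 (DCM)");
  if (nsteps < 1 || stride < 1) stop("nsteps and stride must be >= 1");
  Params q = unpack(pars);
  int nsamp = nsteps / stride + ((nsteps % stride) ? 2 : 1);
  NumericMatrix out(nsamp, 13);
  double y[18], k1[18], k2[18], k3[18], k4[18], tmp[18];
  if (state0.size() == 12) {
    double R[3][3];
    rotmat(state0[6], state0[7], state0[8], R);
    for (int i = 0; i < 6; ++i) y[i] = state0[i];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) y[6 + 3 * i + j] = R[i][j];
    for (int i = 0; i < 3; ++i) y[15 + i] = state0[9 + i];
  } else {
    for (int i = 0; i < 18; ++i) y[i] = state0[i];
  }
  int row = 0;
  write_sample(out, row++, step0 * dt, y);
  for (int s = 1; s <= nsteps; ++s) {
    double t = (step0 + s - 1) * dt;
    deriv18(q, t, y, k1);
    for (int i = 0; i < 18; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    deriv18(q, t + 0.5 * dt, tmp, k2);
    for (int i = 0; i < 18; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    deriv18(q, t + 0.5 * dt, tmp, k3);
    for (int i = 0; i < 18; ++i) tmp[i] = y[i] + dt * k3[i];
    deriv18(q, t + dt, tmp, k4);
    for (int i = 0; i < 18; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    renormalize(y);
    if (!std::isfinite(y[0]) || !std::isfinite(y[3]) || !std::isfinite(y[15]))
      stop("integration diverged: non-finite state at t = %g", t + dt);
    if (s % stride == 0 || s == nsteps)
      write_sample(out, row++, (step0 + s) * dt, y);
  }
  if (row < nsamp) out = out(Range(0, row - 1), Range(0, 12));
  NumericVector fin(18);
  for (int i = 0; i < 18; ++i) fin[i] = y[i];
  return List::create(Named("samples") = out, Named("state") = fin);
}
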