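// Lagrangian tracking of cell-sized particles through the composite lumen
// flow field (Poiseuille axial + interpolated swirl w(r,z)).
//
// Two integration modes:
//  * mode 0, "equilibrium": overdamped closure
//      u_p = u + v_s*ghat + tau_p*(w^2/r)*rhat   (+ entrance drift),
//    advanced with RK4 in Cartesian coordinates. The path step is capped both
//    by the protocol path step and by an angular step bound; explicit schemes
//    stepped a full path step through near-solid-body swirl would otherwise
//    generate a spurious outward numerical spiral.
//  * mode 1, "full": the inertial particle momentum equation
//      dv/dt = (u - v)/tau_p + g*(rho_p - rho)/rho_p
//    with the linear drag integrated exactly over each step (exponential
//    update, stable despite tau_p ~ 5.8e-6 s) and a Heun (two-stage)
//    position update. Serves as the stiff oracle for the equilibrium mode.
//
// Fates: 1 = trapped (wall contact with 0 <= z <= L), 2 = escaped (z >= L
// before wall contact), 3 = incomplete (path length cap reached).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Field {
  const double *rg, *zg, *uz, *W;
  int nr, nz;
  double R, L, entrance_len;
  double inv_dr;            // uniform radial grid spacing
  mutable int zhint;        // cached axial bracket (particle z moves slowly)

  int zbracket(double z) const {
    int k = zhint;
    if (k < 0) k = 0;
    if (k > nz - 2) k = nz - 2;
    while (k > 0 && z < zg[k]) --k;
    while (k < nz - 2 && z >= zg[k + 1]) ++k;
    zhint = k;
    return k;
  }

  // swirl w and axial u_z at (r, z) in one pass (shared radial bracket)
  void eval(double r, double z, double &w, double &uzv) const {
    if (r < 0) r = 0;
    if (r > R) r = R;
    double s = r * inv_dr;
    int i = (int)s;
    if (i > nr - 2) i = nr - 2;
    double tr = s - i;
    uzv = uz[i] * (1 - tr) + uz[i + 1] * tr;
    int k = zbracket(z);
    double tz = (z - zg[k]) / (zg[k + 1] - zg[k]);
    if (tz < 0) tz = 0;
    if (tz > 1) tz = 1;
    const double *c0 = W + (size_t)k * nr, *c1 = c0 + nr;
    double w0 = c0[i] * (1 - tr) + c0[i + 1] * tr;
    double w1 = c1[i] * (1 - tr) + c1[i + 1] * tr;
    w = w0 * (1 - tz) + w1 * tz;
  }

  double swirl(double r, double z) const {
    double w, u;
    eval(r, z, w, u);
    return w;
  }

  double axial(double r) const {
    if (r < 0) r = 0;
    if (r > R) return 0;
    double s = r * inv_dr;
    int i = (int)s;
    if (i > nr - 2) i = nr - 2;
    double tr = s - i;
    return uz[i] * (1 - tr) + uz[i + 1] * tr;
  }
};

struct Params {
  double vs, gx, gy;       // settling speed and unit gravity direction
  double tau_p;
  double path_step, max_path;
  double dtheta_max;
  int mode;
  double slope, ex, ey;    // per-particle entrance drift slope + axis fallback dir
};

// fluid velocity as transported by the reduced model (swirl + axial +
// entrance redistribution drift); vout length 3, also returns w and r.
inline void fluid_vel(const Field &F, const Params &P,
                      double x, double y, double z,
                      double *vout, double &w, double &r) {
  r = std::sqrt(x * x + y * y);
  double uzv;
  F.eval(r, z, w, uzv);
  double rx, ry;
  if (r > 1e-14) { rx = x / r; ry = y / r; }
  else { rx = P.ex; ry = P.ey; }
  vout[0] = -w * ry;
  vout[1] = w * rx;
  vout[2] = uzv;
  if (z < F.entrance_len && P.slope != 0.0) {
    // drift dr/dz = 2*slope*(1 - z/Le): integrates to slope*Le over the
    // entrance but decays continuously to zero at z = Le (a velocity jump
    // there would make trajectories step-size sensitive)
    double taper = 2.0 * (1.0 - z / F.entrance_len);
    vout[0] += P.slope * taper * uzv * rx;
    vout[1] += P.slope * taper * uzv * ry;
  }
}

// equilibrium particle velocity
inline void equil_vel(const Field &F, const Params &P,
                      double x, double y, double z, double *vout) {
  double w, r;
  fluid_vel(F, P, x, y, z, vout, w, r);
  vout[0] += P.vs * P.gx;
  vout[1] += P.vs * P.gy;
  if (r > 1e-14) {
    double cf = P.tau_p * w * w / r;
    vout[0] += cf * x / r;
    vout[1] += cf * y / r;
  }
}

// one RK4 step of the equilibrium closure; returns new position
inline void rk4_step(const Field &F, const Params &P, const double *s,
                     double dt, double *out) {
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  equil_vel(F, P, s[0], s[1], s[2], k1);
  for (int j = 0; j < 3; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
  equil_vel(F, P, tmp[0], tmp[1], tmp[2], k2);
  for (int j = 0; j < 3; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
  equil_vel(F, P, tmp[0], tmp[1], tmp[2], k3);
  for (int j = 0; j < 3; ++j) tmp[j] = s[j] + dt * k3[j];
  equil_vel(F, P, tmp[0], tmp[1], tmp[2], k4);
  for (int j = 0; j < 3; ++j)
    out[j] = s[j] + dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
}

// One exponential-trapezoidal (ETD2) step of the full momentum equation,
// state s = (x, y, z, vx, vy, vz). The linear drag is integrated exactly
// with the fluid velocity along the path approximated as linear in time,
//   u(t) = u1 + c t,  c = (u2 - u1)/dt,
// which keeps the O(tau_p) slip response (-tau_p * Du/Dt, the centrifugal
// drift) that a frozen-field exponential update would lose once dt >> tau_p:
//   v(t)  = u(t) + vs*ghat - c*tau + (v0 - u1 - vs*ghat + c*tau) e^(-t/tau)
//   x(dt) = x0 + (u1 + u2)/2 dt + vs*ghat dt
//           + (v0 - u1 - vs*ghat + c*tau) tau (1 - E) - c tau dt
inline void full_step(const Field &F, const Params &P, const double *s,
                      double dt, double *out) {
  double u1[3], u2[3], w, r;
  double tau = P.tau_p;
  double E = std::exp(-dt / tau);
  double gv[3] = {P.vs * P.gx, P.vs * P.gy, 0.0};
  fluid_vel(F, P, s[0], s[1], s[2], u1, w, r);
  // predictor: frozen-field exponential step to locate the stage-2 point
  double x1[3];
  for (int j = 0; j < 3; ++j) {
    double tgt = u1[j] + gv[j];
    x1[j] = s[j] + tgt * dt + (s[3 + j] - tgt) * tau * (1 - E);
  }
  fluid_vel(F, P, x1[0], x1[1], x1[2], u2, w, r);
  for (int j = 0; j < 3; ++j) {
    double c = (u2[j] - u1[j]) / dt;
    double dev = s[3 + j] - u1[j] - gv[j] + c * tau;
    out[j] = s[j] + 0.5 * (u1[j] + u2[j]) * dt + gv[j] * dt +
      dev * tau * (1 - E) - c * tau * dt;
    out[3 + j] = u2[j] + gv[j] - c * tau + dev * E;
  }
}

struct StepResult {
  int fate;       // 0 = in flight
  double t, path;
};

// advance one particle to its fate; optionally record the trajectory
void track(const Field &F, Params &P, double x, double y, double z,
           double *rec /*fate,zend,theta,time,path,x,y*/,
           std::vector<double> *traj, int thin) {
  const int NS = (P.mode == 0) ? 3 : 6;
  double s[6] = {x, y, z, 0, 0, 0};
  if (P.mode == 1) {
    double w, r;
    double u[3];
    fluid_vel(F, P, x, y, z, u, w, r);
    s[3] = u[0]; s[4] = u[1]; s[5] = u[2];
  }
  double t = 0, path = 0;
  long iter = 0;
  const long max_iter = 200000000L;
  int fate = 0;
  double snew[6];
  while (fate == 0) {
    if (++iter > max_iter) stop("particle exceeded the internal iteration cap");
    double r = std::sqrt(s[0] * s[0] + s[1] * s[1]);
    double v[3];
    double speed;
    if (P.mode == 0) {
      equil_vel(F, P, s[0], s[1], s[2], v);
      speed = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    } else {
      speed = std::sqrt(s[3] * s[3] + s[4] * s[4] + s[5] * s[5]);
      double w0 = F.swirl(r, s[2]);
      double fs = std::fabs(w0) + F.axial(r);
      if (fs > speed) speed = fs;
    }
    if (!(speed > 1e-15)) { fate = 3; break; }  // stagnant: give up as incomplete
    double dt = P.path_step / speed;
    double w0 = std::fabs(F.swirl(r, s[2]));
    if (r > 1e-12 && w0 > 1e-15) {
      double dt_ang = P.dtheta_max * r / w0;
      if (dt_ang < dt) dt = dt_ang;
    }
    if (P.mode == 0) rk4_step(F, P, s, dt, snew);
    else full_step(F, P, s, dt, snew);
    for (int j = 0; j < NS; ++j)
      if (!std::isfinite(snew[j])) stop("particle state became non-finite");
    double rn = std::sqrt(snew[0] * snew[0] + snew[1] * snew[1]);
    if (rn >= F.R) {
      // bisect dt for the wall-contact point
      double lo = 0, hi = dt;
      double sc[6];
      for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (lo + hi);
        if (P.mode == 0) rk4_step(F, P, s, mid, sc);
        else full_step(F, P, s, mid, sc);
        double rc = std::sqrt(sc[0] * sc[0] + sc[1] * sc[1]);
        if (rc >= F.R) hi = mid; else lo = mid;
      }
      if (P.mode == 0) rk4_step(F, P, s, hi, sc);
      else full_step(F, P, s, hi, sc);
      double dpath = std::sqrt((sc[0] - s[0]) * (sc[0] - s[0]) +
                               (sc[1] - s[1]) * (sc[1] - s[1]) +
                               (sc[2] - s[2]) * (sc[2] - s[2]));
      t += hi; path += dpath;
      for (int j = 0; j < NS; ++j) s[j] = sc[j];
      fate = (s[2] > F.L) ? 2 : 1;  // beyond the scaffold it crossed z=L first
      if (fate == 2) s[2] = F.L;
      break;
    }
    if (snew[2] >= F.L) {
      double f = (F.L - s[2]) / (snew[2] - s[2]);
      if (!std::isfinite(f) || f < 0) f = 0;
      if (f > 1) f = 1;
      double dpath = 0;
      for (int j = 0; j < 3; ++j) {
        double d = (snew[j] - s[j]) * f;
        dpath += d * d;
        s[j] += d;
      }
      t += f * dt; path += std::sqrt(dpath);
      fate = 2;
      break;
    }
    double dpath = std::sqrt((snew[0] - s[0]) * (snew[0] - s[0]) +
                             (snew[1] - s[1]) * (snew[1] - s[1]) +
                             (snew[2] - s[2]) * (snew[2] - s[2]));
    t += dt; path += dpath;
    for (int j = 0; j < NS; ++j) s[j] = snew[j];
    if (traj && (iter % thin == 0)) {
      traj->push_back(t); traj->push_back(s[0]); traj->push_back(s[1]);
      traj->push_back(s[2]); traj->push_back(path);
    }
    if (path >= P.max_path) { fate = 3; break; }
  }
  double theta = std::atan2(s[0], s[1]) * 180.0 / M_PI;  // from +y (top)
  if (theta < 0) theta += 360.0;
  rec[0] = fate; rec[1] = s[2]; rec[2] = theta; rec[3] = t; rec[4] = path;
  rec[5] = s[0]; rec[6] = s[1];
  if (traj) {
    traj->push_back(t); traj->push_back(s[0]); traj->push_back(s[1]);
    traj->push_back(s[2]); traj->push_back(path);
  }
}

Field make_field(NumericVector rg, NumericVector zg, NumericMatrix W,
                 NumericVector uz, double R, double L, double entrance_len) {
  Field F;
  F.rg = rg.begin(); F.zg = zg.begin(); F.W = W.begin(); F.uz = uz.begin();
  F.nr = rg.size(); F.nz = zg.size();
  F.R = R; F.L = L; F.entrance_len = entrance_len;
  F.inv_dr = (F.nr - 1) / R;
  F.zhint = 0;
  for (int i = 1; i < F.nr; ++i) {
    double expect = R * i / (F.nr - 1);
    if (std::fabs(rg[i] - expect) > 1e-9 * R)
      stop("radial grid must be uniform over [0, R]");
  }
  if (W.nrow() != F.nr || W.ncol() != F.nz)
    stop("swirl matrix dimensions do not match the grids");
  return F;
}

} // namespace

// [[Rcpp::export(name = ".track_particles")]]
NumericMatrix track_particles_cpp(NumericMatrix init,  // cols: r0, theta_rad, slope
                                  NumericVector rg, NumericVector zg,
                                  NumericMatrix W, NumericVector uz,
                                  double R, double L, double entrance_len,
                                  double vs, double gx, double gy,
                                  double tau_p, double path_step, double max_path,
                                  double dtheta_max, int mode) {
  int n = init.nrow();
  Field F = make_field(rg, zg, W, uz, R, L, entrance_len);
  NumericMatrix out(n, 7);
  colnames(out) = CharacterVector::create("fate", "z_m", "theta_deg",
                                          "time_s", "path_length_m", "x_m", "y_m");
  for (int p = 0; p < n; ++p) {
    Params P;
    P.vs = vs; P.gx = gx; P.gy = gy; P.tau_p = tau_p;
    P.path_step = path_step; P.max_path = max_path;
    P.dtheta_max = dtheta_max; P.mode = mode;
    P.slope = init(p, 2);
    double th = init(p, 1);
    P.ex = std::sin(th); P.ey = std::cos(th);
    double x = init(p, 0) * std::sin(th);
    double y = init(p, 0) * std::cos(th);
    double rec[7];
    track(F, P, x, y, 0.0, rec, nullptr, 1);
    for (int j = 0; j < 7; ++j) out(p, j) = rec[j];
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".track_one")]]
List track_one_cpp(double r0, double theta_rad, double slope,
                   NumericVector rg, NumericVector zg,
                   NumericMatrix W, NumericVector uz,
                   double R, double L, double entrance_len,
                   double vs, double gx, double gy,
                   double tau_p, double path_step, double max_path,
                   double dtheta_max, int mode, int thin) {
  Field F = make_field(rg, zg, W, uz, R, L, entrance_len);
  Params P;
  P.vs = vs; P.gx = gx; P.gy = gy; P.tau_p = tau_p;
  P.path_step = path_step; P.max_path = max_path;
  P.dtheta_max = dtheta_max; P.mode = mode;
  P.slope = slope;
  P.ex = std::sin(theta_rad); P.ey = std::cos(theta_rad);
  double x = r0 * std::sin(theta_rad);
  double y = r0 * std::cos(theta_rad);
  std::vector<double> traj;
  traj.push_back(0); traj.push_back(x); traj.push_back(y);
  traj.push_back(0); traj.push_back(0);
  double rec[7];
  track(F, P, x, y, 0.0, rec, &traj, thin < 1 ? 1 : thin);
  int m = traj.size() / 5;
  NumericMatrix tm(m, 5);
  colnames(tm) = CharacterVector::create("time_s", "x_m", "y_m", "z_m",
                                         "path_length_m");
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 5; ++j) tm(i, j) = traj[i * 5 + j];
  NumericVector rv(7);
  rv.names() = CharacterVector::create("fate", "z_m", "theta_deg", "time_s",
                                       "path_length_m", "x_m", "y_m");
  for (int j = 0; j < 7; ++j) rv[j] = rec[j];
  return List::create(_["record"] = rv, _["trajectory"] = tm);
}
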