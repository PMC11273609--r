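// Overdamped rigid-body Brownian dynamics core and trilinear grid
// interpolation.  Units: Angstrom, ns, kJ/mol; forces kJ/mol/Angstrom.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  const double* v;
  int nx, ny, nz;
  double ox, oy, oz, h;
  bool present;
};

Grid as_grid(SEXP g) {
  Grid out;
  out.present = false;
  if (Rf_isNull(g)) return out;
  List gl(g);
  NumericVector vals = gl["values"];
  IntegerVector d = vals.attr("dim");
  NumericVector org = gl["origin"];
  out.v = vals.begin();
  out.nx = d[0]; out.ny = d[1]; out.nz = d[2];
  out.ox = org[0]; out.oy = org[1]; out.oz = org[2];
  out.h = as<double>(gl["spacing"]);
  out.present = true;
  return out;
}

inline double gval(const Grid& g, int i, int j, int k) {
  return g.v[i + g.nx * (j + (R_xlen_t)g.ny * k)];
}

// Trilinear value + gradient at p (clamped to the box).
void interp(const Grid& g, const double p[3], double& e, double grad[3]) {
  double u[3];
  int i0[3], n[3] = {g.nx, g.ny, g.nz};
  double o[3] = {g.ox, g.oy, g.oz};
  double f[3];
  for (int a = 0; a < 3; ++a) {
    u[a] = (p[a] - o[a]) / g.h;
    if (!std::isfinite(u[a])) stop("non-finite position in grid lookup");
    if (u[a] < 0) u[a] = 0;
    if (u[a] > n[a] - 1) u[a] = n[a] - 1;
    i0[a] = (int)std::floor(u[a]);
    if (i0[a] > n[a] - 2) i0[a] = n[a] - 2;
    f[a] = u[a] - i0[a];
  }
  double c[2][2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k)
        c[i][j][k] = gval(g, i0[0] + i, i0[1] + j, i0[2] + k);
  double wx[2] = {1 - f[0], f[0]};
  double wy[2] = {1 - f[1], f[1]};
  double wz[2] = {1 - f[2], f[2]};
  e = 0; grad[0] = grad[1] = grad[2] = 0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k) {
        double cv = c[i][j][k];
        e += cv * wx[i] * wy[j] * wz[k];
        grad[0] += cv * (i == 0 ? -1.0 : 1.0) * wy[j] * wz[k];
        grad[1] += cv * wx[i] * (j == 0 ? -1.0 : 1.0) * wz[k];
        grad[2] += cv * wx[i] * wy[j] * (k == 0 ? -1.0 : 1.0);
      }
  for (int a = 0; a < 3; ++a) grad[a] /= g.h;
}

// quaternion (w,x,y,z) to rotation matrix, body -> world
void quat_to_R(const double q[4], double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z);
  R[0][1] = 2 * (x * y - w * z);
  R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z);
  R[1][1] = 1 - 2 * (x * x + z * z);
  R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y);
  R[2][1] = 2 * (y * z + w * x);
  R[2][2] = 1 - 2 * (x * x + y * y);
}

void quat_mul(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

void quat_from_rotvec(const double r[3], double q[4]) {
  double th = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
  if (th < 1e-12) {
    q[0] = 1; q[1] = 0.5 * r[0]; q[2] = 0.5 * r[1]; q[3] = 0.5 * r[2];
  } else {
    double s = std::sin(th / 2) / th;
    q[0] = std::cos(th / 2);
    q[1] = s * r[0]; q[2] = s * r[1]; q[3] = s * r[2];
  }
  double nrm = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] +
                         q[3] * q[3]);
  for (int a = 0; a < 4; ++a) q[a] /= nrm;
}

struct System {
  NumericMatrix atoms;     // body frame, COM at origin
  NumericVector charge;
  IntegerVector cat;       // 0 H, 1 ON, 2 CS, -1 none
  Grid elec, lj[3];
  // external test potential: 0 none, 1 harmonic, 2 double well (x)
  int ext_type;
  NumericVector ext_par;
  NumericVector box_lo, box_hi;
  double k_wall;
};

// grid (interaction) energy and COM force / body torque at a pose
double eval_forces(const System& S, const double pos[3],
                   const double Rm[3][3], double F[3], double Tq[3]) {
  double E = 0;
  F[0] = F[1] = F[2] = 0;
  Tq[0] = Tq[1] = Tq[2] = 0;
  int n = S.atoms.nrow();
  for (int i = 0; i < n; ++i) {
    double xb[3] = {S.atoms(i, 0), S.atoms(i, 1), S.atoms(i, 2)};
    double rw[3];
    for (int a = 0; a < 3; ++a)
      rw[a] = Rm[a][0] * xb[0] + Rm[a][1] * xb[1] + Rm[a][2] * xb[2];
    double pw[3] = {pos[0] + rw[0], pos[1] + rw[1], pos[2] + rw[2]};
    double fi[3] = {0, 0, 0};
    double e, g[3];
    if (S.elec.present && S.charge[i] != 0) {
      interp(S.elec, pw, e, g);
      E += S.charge[i] * e;
      for (int a = 0; a < 3; ++a) fi[a] -= S.charge[i] * g[a];
    }
    int c = S.cat[i];
    if (c >= 0 && S.lj[c].present) {
      interp(S.lj[c], pw, e, g);
      E += e;
      for (int a = 0; a < 3; ++a) fi[a] -= g[a];
    }
    F[0] += fi[0]; F[1] += fi[1]; F[2] += fi[2];
    Tq[0] += rw[1] * fi[2] - rw[2] * fi[1];
    Tq[1] += rw[2] * fi[0] - rw[0] * fi[2];
    Tq[2] += rw[0] * fi[1] - rw[1] * fi[0];
  }
  return E;
}

// external test potential + confining wall act on the COM
void com_forces(const System& S, const double pos[3], double F[3]) {
  if (S.ext_type == 1) {            // harmonic: k, cx, cy, cz
    double k = S.ext_par[0];
    for (int a = 0; a < 3; ++a) F[a] -= k * (pos[a] - S.ext_par[1 + a]);
  } else if (S.ext_type == 2) {     // double well in x: h, c, w
    double h = S.ext_par[0], c = S.ext_par[1], w = S.ext_par[2];
    double u = pos[0] - c;
    // U = h ((u^2 - w^2)/w^2)^2 ; dU/du = 4 h u (u^2 - w^2) / w^4
    F[0] -= 4 * h * u * (u * u - w * w) / (w * w * w * w);
  }
  if (S.box_lo.size() == 3) {
    for (int a = 0; a < 3; ++a) {
      if (pos[a] < S.box_lo[a]) F[a] += S.k_wall * (S.box_lo[a] - pos[a]);
      if (pos[a] > S.box_hi[a]) F[a] -= S.k_wall * (pos[a] - S.box_hi[a]);
    }
  }
}

System make_system(NumericMatrix atoms, NumericVector charge,
                   IntegerVector cat, List grids, int ext_type,
                   NumericVector ext_par, NumericVector box_lo,
                   NumericVector box_hi, double k_wall) {
  System S{atoms, charge, cat,
           as_grid(grids.containsElementNamed("electrostatic")
                   ? grids["electrostatic"] : R_NilValue),
           {as_grid(grids.containsElementNamed("LJ_H")
                    ? grids["LJ_H"] : R_NilValue),
            as_grid(grids.containsElementNamed("LJ_ON")
                    ? grids["LJ_ON"] : R_NilValue),
            as_grid(grids.containsElementNamed("LJ_CS")
                    ? grids["LJ_CS"] : R_NilValue)},
           ext_type, ext_par, box_lo, box_hi, k_wall};
  return S;
}

}  // namespace

// [[Rcpp::export]]
List cpp_interp_trilinear(NumericVector values, NumericVector origin,
                          double spacing, NumericMatrix points,
                          double k_wall) {
  List gl = List::create(_["values"] = values, _["origin"] = origin,
                         _["spacing"] = spacing);
  Grid g = as_grid(gl);
  int n = points.nrow();
  NumericVector energy(n);
  NumericMatrix grad(n, 3);
  double hi[3] = {g.ox + g.h * (g.nx - 1), g.oy + g.h * (g.ny - 1),
                  g.oz + g.h * (g.nz - 1)};
  double lo[3] = {g.ox, g.oy, g.oz};
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double e, gr[3];
    interp(g, p, e, gr);
    for (int a = 0; a < 3; ++a) {
      double d = 0;
      if (p[a] < lo[a]) d = p[a] - lo[a];
      if (p[a] > hi[a]) d = p[a] - hi[a];
      e += 0.5 * k_wall * d * d;
      gr[a] += k_wall * d;
      grad(i, a) = gr[a];
    }
    energy[i] = e;
  }
  return List::create(_["energy"] = energy, _["gradient"] = grad);
}

// [[Rcpp::export]]
double cpp_pose_energy(NumericMatrix atoms, NumericVector charge,
                       IntegerVector cat, List grids, NumericVector pos,
                       NumericVector quat) {
  System S = make_system(atoms, charge, cat, grids, 0,
                         NumericVector(0), NumericVector(0),
                         NumericVector(0), 0.0);
  double q[4] = {quat[0], quat[1], quat[2], quat[3]};
  double Rm[3][3];
  quat_to_R(q, Rm);
  double p[3] = {pos[0], pos[1], pos[2]};
  double F[3], Tq[3];
  return eval_forces(S, p, Rm, F, Tq);
}

// [[Rcpp::export]]
List cpp_bd_run(NumericMatrix atoms, NumericVector charge,
                IntegerVector cat, List grids, NumericVector D_trans,
                NumericVector D_rot, double temperature_K,
                double dt_ns, double n_steps_d, int record_every,
                NumericVector pos0, NumericVector quat0, int ext_type,
                NumericVector ext_par, NumericVector box_lo,
                NumericVector box_hi, double k_wall, bool thermal,
                bool pulling, double k_pull,
                NumericVector pull_from, NumericVector pull_vel) {
  const double kBT = 0.008314462 * temperature_K;
  R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  System S = make_system(atoms, charge, cat, grids, ext_type, ext_par,
                         box_lo, box_hi, k_wall);
  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double q[4] = {quat0[0], quat0[1], quat0[2], quat0[3]};

  R_xlen_t n_frames = n_steps / record_every + 1;
  NumericVector times(n_frames), energies(n_frames);
  NumericMatrix positions(n_frames, 3), quats(n_frames, 4);
  NumericMatrix restraint(pulling ? n_frames : 0, 3);

  double sT[3], sR[3];
  for (int a = 0; a < 3; ++a) {
    sT[a] = thermal ? std::sqrt(2 * D_trans[a] * dt_ns) : 0.0;
    sR[a] = thermal ? std::sqrt(2 * D_rot[a] * dt_ns) : 0.0;
  }

  R_xlen_t frame = 0;
  for (R_xlen_t step = 0; step <= n_steps; ++step) {
    double Rm[3][3];
    quat_to_R(q, Rm);
    double F[3], Tq[3];
    double E = eval_forces(S, pos, Rm, F, Tq);

    if (step % record_every == 0) {
      times[frame] = step * dt_ns;
      energies[frame] = E;
      for (int a = 0; a < 3; ++a) positions(frame, a) = pos[a];
      for (int a = 0; a < 4; ++a) quats(frame, a) = q[a];
      if (pulling)
        for (int a = 0; a < 3; ++a)
          restraint(frame, a) = pull_from[a] + pull_vel[a] * step * dt_ns;
      ++frame;
    }
    if (step == n_steps) break;

    com_forces(S, pos, F);
    if (pulling) {
      double t = step * dt_ns;
      for (int a = 0; a < 3; ++a) {
        double c = pull_from[a] + pull_vel[a] * t;
        F[a] -= k_pull * (pos[a] - c);
      }
    }
    for (int a = 0; a < 3; ++a) {
      if (!std::isfinite(F[a]) || !std::isfinite(Tq[a]))
        stop("non-finite force or torque at step %ld", (long)step);
    }

    // body-frame overdamped updates (D diagonal in the body frame)
    double Fb[3], Tb[3], dxb[3], dthb[3];
    for (int a = 0; a < 3; ++a) {
      Fb[a] = Rm[0][a] * F[0] + Rm[1][a] * F[1] + Rm[2][a] * F[2];
      Tb[a] = Rm[0][a] * Tq[0] + Rm[1][a] * Tq[1] + Rm[2][a] * Tq[2];
    }
    for (int a = 0; a < 3; ++a) {
      double xiT = thermal ? norm_rand() : 0.0;
      double xiR = thermal ? norm_rand() : 0.0;
      dxb[a] = D_trans[a] / kBT * Fb[a] * dt_ns + sT[a] * xiT;
      dthb[a] = D_rot[a] / kBT * Tb[a] * dt_ns + sR[a] * xiR;
    }
    for (int a = 0; a < 3; ++a)
      pos[a] += Rm[a][0] * dxb[0] + Rm[a][1] * dxb[1] + Rm[a][2] * dxb[2];
    if (!std::isfinite(pos[0]) || !std::isfinite(pos[1]) ||
        !std::isfinite(pos[2]))
      stop("position diverged at step %ld; reduce the time step",
           (long)step);
    double dq[4], qn[4];
    quat_from_rotvec(dthb, dq);
    quat_mul(q, dq, qn);
    double nrm = std::sqrt(qn[0] * qn[0] + qn[1] * qn[1] +
                           qn[2] * qn[2] + qn[3] * qn[3]);
    for (int a = 0; a < 4; ++a) q[a] = qn[a] / nrm;
  }

  List out = List::create(_["time_ns"] = times, _["positions"] = positions,
                          _["quaternions"] = quats,
                          _["energy_kJ_mol"] = energies);
  if (pulling) out["restraint"] = restraint;
  return out;
}
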