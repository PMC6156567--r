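// Two-state EVB engine: diabatic energies/forces for a toy donor-H-acceptor
// droplet, leapfrog dynamics with Berendsen thermostat and SHAKE, and a
// steepest-descent minimizer. Units: kcal/mol, Angstrom, fs, amu, e.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double COULOMB = 332.06;   // kcal A mol^-1 e^-2
static const double KB = 1.9872e-3;     // kcal mol^-1 K^-1
static const double MD_ACC = 4.184e-4;  // (kcal/mol/A)/amu -> A/fs^2

struct StateFF {
  std::vector<double> q;
  std::vector<double> morse;   // rows: i j D beta r0 (0-based indices)
  std::vector<double> bonds;   // i j k r0
  std::vector<double> angles;  // i j k ktheta theta0_deg
  int n_morse, n_bonds, n_angles;
};

struct System {
  int n;
  std::vector<double> mass, lj_sigma, lj_eps;
  StateFF st[2];
  std::vector<unsigned char> excl;  // n*n, bit0 = excluded in state1, bit1 state2
  double alpha;
  double cutoff;
  std::vector<unsigned char> reacting;
  double wall_radius, wall_k;
  std::vector<double> posres;   // atom k x y z
  std::vector<double> distres;  // i j k r0
  std::vector<double> constr;   // i j d
  int n_posres, n_distres, n_constr;
};

static std::vector<double> flat(const NumericMatrix& m, int& nrow) {
  nrow = m.nrow();
  std::vector<double> out(m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out[i * m.ncol() + j] = m(i, j);
  return out;
}

static System unpack(const List& pack) {
  System s;
  NumericVector mass = pack["mass"], sg = pack["lj_sigma"], ep = pack["lj_eps"];
  s.mass.assign(mass.begin(), mass.end());
  s.lj_sigma.assign(sg.begin(), sg.end());
  s.lj_eps.assign(ep.begin(), ep.end());
  s.n = s.mass.size();
  s.excl.assign((size_t)s.n * s.n, 0);
  List states = pack["states"];
  for (int k = 0; k < 2; ++k) {
    List st = states[k];
    NumericVector q = st["charges"];
    s.st[k].q.assign(q.begin(), q.end());
    s.st[k].morse = flat(st["morse"], s.st[k].n_morse);
    s.st[k].bonds = flat(st["bonds"], s.st[k].n_bonds);
    s.st[k].angles = flat(st["angles"], s.st[k].n_angles);
    NumericMatrix ex = as<NumericMatrix>(st["exclusions"]);
    for (int e = 0; e < ex.nrow(); ++e) {
      int i = (int)ex(e, 0) - 1, j = (int)ex(e, 1) - 1;
      s.excl[(size_t)i * s.n + j] |= (1 << k);
      s.excl[(size_t)j * s.n + i] |= (1 << k);
    }
  }
  s.alpha = as<double>(pack["alpha"]);
  s.cutoff = as<double>(pack["cutoff"]);
  s.reacting.assign(s.n, 0);
  IntegerVector rx = pack["reacting"];
  for (int i = 0; i < rx.size(); ++i) s.reacting[rx[i] - 1] = 1;
  s.wall_radius = as<double>(pack["wall_radius"]);
  s.wall_k = as<double>(pack["wall_k"]);
  s.posres = flat(as<NumericMatrix>(pack["posres"]), s.n_posres);
  s.distres = flat(as<NumericMatrix>(pack["distres"]), s.n_distres);
  s.constr = flat(as<NumericMatrix>(pack["constraints"]), s.n_constr);
  return s;
}

// Diabatic energies and forces at coordinates x (length 3n, xyz-interleaved).
// e2 is returned WITHOUT the gas-phase shift alpha.
static void eval_states(const System& s, const double* x,
                        double& e1, double& e2, double* f1, double* f2) {
  const int n = s.n;
  e1 = e2 = 0.0;
  std::fill(f1, f1 + 3 * n, 0.0);
  std::fill(f2, f2 + 3 * n, 0.0);

  const double cut2 = s.cutoff * s.cutoff;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
    const double si = s.lj_sigma[i], ei = s.lj_eps[i];
    const double q1i = s.st[0].q[i], q2i = s.st[1].q[i];
    const bool ri = s.reacting[i];
    const unsigned char* exrow = &s.excl[(size_t)i * n];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[3*j], dy = yi - x[3*j+1], dz = zi - x[3*j+2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 0.01)
        stop("overlapping atoms %d and %d (r = %.3f A < 0.1 A)",
             i + 1, j + 1, std::sqrt(r2));
      unsigned char ex = exrow[j];
      if (ex == 3) continue;
      if (!(ri || s.reacting[j]) && r2 > cut2) continue;
      double invr2 = 1.0 / r2;
      double invr = std::sqrt(invr2);
      double elj = 0.0, dlj_r = 0.0;  // dlj_r = (dE/dr)/r
      double eij = s.lj_eps[j] > 0.0 && ei > 0.0 ? std::sqrt(ei * s.lj_eps[j]) : 0.0;
      if (eij > 0.0) {
        double sij = 0.5 * (si + s.lj_sigma[j]);
        double sr2 = sij * sij * invr2;
        double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        elj = 4.0 * eij * (sr12 - sr6);
        dlj_r = 4.0 * eij * (-12.0 * sr12 + 6.0 * sr6) * invr2;
      }
      if (!(ex & 1)) {
        double qq = COULOMB * q1i * s.st[0].q[j];
        double ec = qq * invr;
        e1 += elj + ec;
        double ded_r = dlj_r - ec * invr2;  // (dE/dr)/r
        f1[3*i]   -= ded_r * dx; f1[3*i+1] -= ded_r * dy; f1[3*i+2] -= ded_r * dz;
        f1[3*j]   += ded_r * dx; f1[3*j+1] += ded_r * dy; f1[3*j+2] += ded_r * dz;
      }
      if (!(ex & 2)) {
        double qq = COULOMB * q2i * s.st[1].q[j];
        double ec = qq * invr;
        e2 += elj + ec;
        double ded_r = dlj_r - ec * invr2;
        f2[3*i]   -= ded_r * dx; f2[3*i+1] -= ded_r * dy; f2[3*i+2] -= ded_r * dz;
        f2[3*j]   += ded_r * dx; f2[3*j+1] += ded_r * dy; f2[3*j+2] += ded_r * dz;
      }
    }
  }

  for (int k = 0; k < 2; ++k) {
    double* f = (k == 0) ? f1 : f2;
    double& etot = (k == 0) ? e1 : e2;
    const StateFF& st = s.st[k];
    for (int b = 0; b < st.n_morse; ++b) {
      const double* row = &st.morse[b * 5];
      int i = (int)row[0] - 1, j = (int)row[1] - 1;
      double D = row[2], beta = row[3], r0 = row[4];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double exm = std::exp(-beta * (r - r0));
      etot += D * (1.0 - exm) * (1.0 - exm);
      double ded_r = 2.0 * D * beta * (1.0 - exm) * exm / r;
      f[3*i]   -= ded_r * dx; f[3*i+1] -= ded_r * dy; f[3*i+2] -= ded_r * dz;
      f[3*j]   += ded_r * dx; f[3*j+1] += ded_r * dy; f[3*j+2] += ded_r * dz;
    }
    for (int b = 0; b < st.n_bonds; ++b) {
      const double* row = &st.bonds[b * 4];
      int i = (int)row[0] - 1, j = (int)row[1] - 1;
      double kb = row[2], r0 = row[3];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      etot += kb * (r - r0) * (r - r0);
      double ded_r = 2.0 * kb * (r - r0) / r;
      f[3*i]   -= ded_r * dx; f[3*i+1] -= ded_r * dy; f[3*i+2] -= ded_r * dz;
      f[3*j]   += ded_r * dx; f[3*j+1] += ded_r * dy; f[3*j+2] += ded_r * dz;
    }
    for (int b = 0; b < st.n_angles; ++b) {
      const double* row = &st.angles[b * 5];
      int i = (int)row[0] - 1, j = (int)row[1] - 1, l = (int)row[2] - 1;
      double ka = row[3], th0 = row[4] * M_PI / 180.0;
      double rij[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
      double rlj[3] = { x[3*l]-x[3*j], x[3*l+1]-x[3*j+1], x[3*l+2]-x[3*j+2] };
      double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
      double nlj = std::sqrt(rlj[0]*rlj[0]+rlj[1]*rlj[1]+rlj[2]*rlj[2]);
      double cth = (rij[0]*rlj[0]+rij[1]*rlj[1]+rij[2]*rlj[2]) / (nij * nlj);
      cth = std::max(-1.0, std::min(1.0, cth));
      double th = std::acos(cth);
      etot += ka * (th - th0) * (th - th0);
      double dedth = 2.0 * ka * (th - th0);
      double sth = std::sqrt(std::max(1.0 - cth * cth, 1e-12));
      for (int d = 0; d < 3; ++d) {
        double di = (rij[d] / nij * cth - rlj[d] / nlj) / (nij * sth);
        double dl = (rlj[d] / nlj * cth - rij[d] / nij) / (nlj * sth);
        f[3*i+d] += -dedth * di;
        f[3*l+d] += -dedth * dl;
        f[3*j+d] += dedth * (di + dl);
      }
    }
  }

  // state-independent restraints: droplet wall, position, distance
  if (s.wall_k > 0.0) {
    for (int i = 0; i < s.n; ++i) {
      double r = std::sqrt(x[3*i]*x[3*i] + x[3*i+1]*x[3*i+1] + x[3*i+2]*x[3*i+2]);
      if (r > s.wall_radius) {
        double d = r - s.wall_radius;
        double e = 0.5 * s.wall_k * d * d;
        e1 += e; e2 += e;
        double ded_r = s.wall_k * d / r;
        for (int dd = 0; dd < 3; ++dd) {
          f1[3*i+dd] -= ded_r * x[3*i+dd];
          f2[3*i+dd] -= ded_r * x[3*i+dd];
        }
      }
    }
  }
  for (int p = 0; p < s.n_posres; ++p) {
    const double* row = &s.posres[p * 5];
    int i = (int)row[0] - 1;
    double kp = row[1];
    if (kp <= 0.0) continue;
    double d[3] = { x[3*i]-row[2], x[3*i+1]-row[3], x[3*i+2]-row[4] };
    double e = 0.5 * kp * (d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    e1 += e; e2 += e;
    for (int dd = 0; dd < 3; ++dd) {
      f1[3*i+dd] -= kp * d[dd]; f2[3*i+dd] -= kp * d[dd];
    }
  }
  for (int p = 0; p < s.n_distres; ++p) {
    const double* row = &s.distres[p * 4];
    int i = (int)row[0] - 1, j = (int)row[1] - 1;
    double kd = row[2], r0 = row[3];
    double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double e = 0.5 * kd * (r - r0) * (r - r0);
    e1 += e; e2 += e;
    double ded_r = kd * (r - r0) / r;
    f1[3*i] -= ded_r * dx; f1[3*i+1] -= ded_r * dy; f1[3*i+2] -= ded_r * dz;
    f1[3*j] += ded_r * dx; f1[3*j+1] += ded_r * dy; f1[3*j+2] += ded_r * dz;
    f2[3*i] -= ded_r * dx; f2[3*i+1] -= ded_r * dy; f2[3*i+2] -= ded_r * dz;
    f2[3*j] += ded_r * dx; f2[3*j+1] += ded_r * dy; f2[3*j+2] += ded_r * dz;
  }
}

static NumericMatrix to_mat(const std::vector<double>& v, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = v[3*i + d];
  return m;
}
static std::vector<double> from_mat(const NumericMatrix& m) {
  std::vector<double> v(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int d = 0; d < 3; ++d) v[3*i + d] = m(i, d);
  return v;
}

// [[Rcpp::export(name = ".evb_eval_cpp")]]
List evb_eval_cpp(List pack, NumericMatrix xyz) {
  System s = unpack(pack);
  if (xyz.nrow() != s.n) stop("coordinate/atom count mismatch");
  std::vector<double> x = from_mat(xyz), f1(3 * s.n), f2(3 * s.n);
  double e1, e2;
  eval_states(s, x.data(), e1, e2, f1.data(), f2.data());
  return List::create(_["e1"] = e1, _["e2_raw"] = e2, _["e2p"] = e2 + s.alpha,
                      _["f1"] = to_mat(f1, s.n), _["f2"] = to_mat(f2, s.n));
}

// SHAKE position corrections against the pre-step geometry.
static void shake(const System& s, const double* xold, double* x,
                  double tol, int maxit) {
  if (s.n_constr == 0) return;
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (int p = 0; p < s.n_constr; ++p) {
      const double* row = &s.constr[p * 3];
      int i = (int)row[0] - 1, j = (int)row[1] - 1;
      double d = row[2];
      double rx = x[3*i]-x[3*j], ry = x[3*i+1]-x[3*j+1], rz = x[3*i+2]-x[3*j+2];
      double r2 = rx*rx + ry*ry + rz*rz;
      if (std::fabs(std::sqrt(r2) - d) > tol) {
        done = false;
        double sx = xold[3*i]-xold[3*j], sy = xold[3*i+1]-xold[3*j+1],
               sz = xold[3*i+2]-xold[3*j+2];
        double dot = rx*sx + ry*sy + rz*sz;
        double invm = 1.0 / s.mass[i] + 1.0 / s.mass[j];
        double g = (r2 - d * d) / (2.0 * invm * dot);
        x[3*i] -= g / s.mass[i] * sx; x[3*i+1] -= g / s.mass[i] * sy;
        x[3*i+2] -= g / s.mass[i] * sz;
        x[3*j] += g / s.mass[j] * sx; x[3*j+1] += g / s.mass[j] * sy;
        x[3*j+2] += g / s.mass[j] * sz;
      }
    }
    if (done) return;
  }
  stop("SHAKE did not converge within %d iterations", maxit);
}

// Leapfrog MD on the mapping potential Em = (1-lambda) e1 + lambda (e2 + alpha).
// Velocities enter at the half step; Berendsen scaling optional. Samples of
// (e1, e2_raw, kinetic energy) are recorded every `stride` steps.
// [[Rcpp::export(name = ".evb_md_cpp")]]
List evb_md_cpp(List pack, NumericMatrix xyz, NumericMatrix vel, double lambda,
                int n_steps, double dt, double temp_K, double tau_fs,
                bool thermostat, int stride, double shake_tol, int shake_maxit,
                bool record_traj) {
  System s = unpack(pack);
  const int n = s.n;
  if (xyz.nrow() != n || vel.nrow() != n) stop("coordinate/velocity size mismatch");
  std::vector<double> x = from_mat(xyz), v = from_mat(vel);
  std::vector<double> f1(3 * n), f2(3 * n), xold(3 * n);
  int ndof = 3 * n - s.n_constr;

  int nsamp = n_steps / stride;
  NumericMatrix samples(nsamp, 3);
  List traj;
  if (record_traj) traj = List(nsamp);
  int isamp = 0;
  double e1, e2;
  const double lam1 = 1.0 - lambda;

  for (int step = 0; step < n_steps; ++step) {
    eval_states(s, x.data(), e1, e2, f1.data(), f2.data());
    double em = lam1 * e1 + lambda * (e2 + s.alpha);
    if (!std::isfinite(em) || std::fabs(em) > 1e6)
      stop("energy blow-up at step %d (Em = %g kcal/mol)", step, em);

    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * s.mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    ke /= MD_ACC;

    if (step % stride == 0 && isamp < nsamp) {
      samples(isamp, 0) = e1;
      samples(isamp, 1) = e2;
      samples(isamp, 2) = ke;
      if (record_traj) traj[isamp] = to_mat(x, n);
      ++isamp;
    }

    if (thermostat) {
      double tinst = 2.0 * ke / (ndof * KB);
      if (tinst > 1e-9) {
        double lam = std::sqrt(1.0 + dt / tau_fs * (temp_K / tinst - 1.0));
        lam = std::max(0.8, std::min(1.25, lam));
        for (int i = 0; i < 3 * n; ++i) v[i] *= lam;
      }
    }

    std::copy(x.begin(), x.end(), xold.begin());
    for (int i = 0; i < n; ++i) {
      double fac = MD_ACC * dt / s.mass[i];
      for (int d = 0; d < 3; ++d) {
        v[3*i+d] += fac * (lam1 * f1[3*i+d] + lambda * f2[3*i+d]);
        x[3*i+d] += v[3*i+d] * dt;
      }
    }
    shake(s, xold.data(), x.data(), shake_tol, shake_maxit);
    const double invdt = 1.0 / dt;
    for (int i = 0; i < 3 * n; ++i) v[i] = (x[i] - xold[i]) * invdt;
  }

  List out = List::create(_["samples"] = samples, _["coords"] = to_mat(x, n),
                          _["vel"] = to_mat(v, n), _["ndof"] = ndof);
  if (record_traj) out["traj"] = traj;
  return out;
}

// Steepest-descent minimization on the mapping potential with backtracking.
// [[Rcpp::export(name = ".evb_min_cpp")]]
List evb_min_cpp(List pack, NumericMatrix xyz, double lambda, int n_steps,
                 double step0) {
  System s = unpack(pack);
  const int n = s.n;
  std::vector<double> x = from_mat(xyz), f1(3*n), f2(3*n), g1(3*n), g2(3*n),
                      xt(3*n);
  double e1, e2, t1, t2;
  eval_states(s, x.data(), e1, e2, f1.data(), f2.data());
  double em = (1.0 - lambda) * e1 + lambda * (e2 + s.alpha);
  double step = step0;
  for (int it = 0; it < n_steps; ++it) {
    double fmax = 1e-12;
    for (int i = 0; i < 3 * n; ++i) {
      double fm = (1.0 - lambda) * f1[i] + lambda * f2[i];
      fmax = std::max(fmax, std::fabs(fm));
    }
    for (int i = 0; i < 3 * n; ++i) {
      double fm = (1.0 - lambda) * f1[i] + lambda * f2[i];
      xt[i] = x[i] + step / fmax * fm;
    }
    eval_states(s, xt.data(), t1, t2, g1.data(), g2.data());
    double emt = (1.0 - lambda) * t1 + lambda * (t2 + s.alpha);
    if (emt < em) {
      x = xt; em = emt; f1 = g1; f2 = g2;
      step = std::min(step * 1.2, 0.5);
    } else {
      step *= 0.5;
      if (step < 1e-8) break;
    }
  }
  return List::create(_["coords"] = to_mat(x, n), _["energy"] = em);
}
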