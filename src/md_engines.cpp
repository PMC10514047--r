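// Lightweight MD engines used by the synthetic-data generators.
//
// (1) Rigid four-site water in a cubic box, NVT.  Velocity Verlet for the
//     centers of mass combined with the exact NO_SQUISH free-rotor
//     splitting for the rigid-body rotation (sequential exact rotations
//     about the principal axes, symplectic and time reversible), a
//     canonical-sampling velocity rescaling (CSVR) thermostat,
//     Lennard-Jones on the oxygen, reaction-field (epsilon_rf = infinity)
//     electrostatics on H/H/M, molecule-based cutoff on the O-O distance.
//     Units: nm, ps, amu, kJ/mol (1 amu nm^2 ps^-2 = 1 kJ/mol, so no
//     conversion constants appear).  Emits per-molecule COM velocities and
//     principal-frame angular velocities, which is exactly what the 2PT
//     machinery consumes.
//
// (2) A purely repulsive soft-sphere fluid integrated with BAOAB Langevin
//     dynamics; a cheap stand-in for a disordered liquid in structural
//     tests.
//
// Both engines are deterministic for a fixed seed (std::mt19937_64).

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.008314462618; // kJ/mol/K

struct WaterSystem {
  int n;
  double box, rc2, rsw, rc, krf, crf;
  double sigma6, eps4, M;
  std::vector<double> sq;          // site charges
  std::vector<double> sl;          // site local coords (ns x 3, row major)
  double Ib[3];
  int ns;
  std::vector<double> r, v;        // com position / velocity
  std::vector<double> A;           // body->lab rotation matrices (n x 9)
  std::vector<double> Lb;          // body-frame angular momentum
  std::vector<double> F, T;        // com force, body torque
  std::vector<double> sp;          // site lab positions (n*ns*3)
  double epot;
};

// A <- A * R_k(phi) and Lb <- R_k(phi)^T Lb : exact free rotation about
// body principal axis k
static inline void rotate_body(double *A, double *Lb, int k, double phi) {
  int i = (k + 1) % 3, j = (k + 2) % 3;
  double c = std::cos(phi), s = std::sin(phi);
  for (int a = 0; a < 3; ++a) {
    double ai = A[a * 3 + i], aj = A[a * 3 + j];
    A[a * 3 + i] = c * ai + s * aj;
    A[a * 3 + j] = -s * ai + c * aj;
  }
  double li = Lb[i], lj = Lb[j];
  Lb[i] = c * li + s * lj;
  Lb[j] = -s * li + c * lj;
}

// NO_SQUISH 5-stage free rotation over dt (axes z, y, x, y, z)
static inline void free_rotation(WaterSystem &S, int m, double dt) {
  double *A = &S.A[m * 9], *Lb = &S.Lb[m * 3];
  const int seq[5] = {2, 1, 0, 1, 2};
  const double fac[5] = {0.5, 0.5, 1.0, 0.5, 0.5};
  for (int s = 0; s < 5; ++s) {
    int k = seq[s];
    double phi = fac[s] * dt * Lb[k] / S.Ib[k];
    rotate_body(A, Lb, k, phi);
  }
}

static inline void gram_schmidt(double *A) {
  // columns are body axes in the lab frame; re-orthonormalize
  double c[3][3];
  for (int b = 0; b < 3; ++b)
    for (int a = 0; a < 3; ++a) c[b][a] = A[a * 3 + b];
  auto norm = [](double *v) {
    double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    v[0] /= n; v[1] /= n; v[2] /= n;
  };
  norm(c[0]);
  double d = c[0][0] * c[1][0] + c[0][1] * c[1][1] + c[0][2] * c[1][2];
  for (int a = 0; a < 3; ++a) c[1][a] -= d * c[0][a];
  norm(c[1]);
  c[2][0] = c[0][1] * c[1][2] - c[0][2] * c[1][1];
  c[2][1] = c[0][2] * c[1][0] - c[0][0] * c[1][2];
  c[2][2] = c[0][0] * c[1][1] - c[0][1] * c[1][0];
  for (int b = 0; b < 3; ++b)
    for (int a = 0; a < 3; ++a) A[a * 3 + b] = c[b][a];
}

static void compute_forces(WaterSystem &S, double fmax) {
  int n = S.n, ns = S.ns;
  std::fill(S.F.begin(), S.F.end(), 0.0);
  std::fill(S.T.begin(), S.T.end(), 0.0);
  S.epot = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *A = &S.A[i * 9];
    for (int s = 0; s < ns; ++s)
      for (int a = 0; a < 3; ++a) {
        double x = 0;
        for (int b = 0; b < 3; ++b) x += A[a * 3 + b] * S.sl[s * 3 + b];
        S.sp[(i * ns + s) * 3 + a] = S.r[i * 3 + a] + x;
      }
  }
  std::vector<double> sf(n * ns * 3, 0.0); // site forces
  std::vector<double> pf(2 * ns * 3);      // per-pair site forces
  double box = S.box;
  for (int i = 0; i < n; ++i) {
    const double *oi = &S.sp[(i * ns) * 3];
    for (int j = i + 1; j < n; ++j) {
      const double *oj = &S.sp[(j * ns) * 3];
      double sh[3], d[3], r2 = 0;
      for (int a = 0; a < 3; ++a) {
        d[a] = oi[a] - oj[a];
        sh[a] = -box * std::nearbyint(d[a] / box);
        d[a] += sh[a];
        r2 += d[a] * d[a];
      }
      if (r2 >= S.rc2) continue;
      std::fill(pf.begin(), pf.end(), 0.0);
      double upair = 0.0;
      // LJ O-O
      {
        double ir2 = 1.0 / r2, s6 = S.sigma6 * ir2 * ir2 * ir2, s12 = s6 * s6;
        double fs = S.eps4 * (12.0 * s12 - 6.0 * s6) * ir2;
        upair += S.eps4 * (s12 - s6);
        for (int a = 0; a < 3; ++a) {
          double fa = fs * d[a];
          pf[a] += fa;
          pf[(ns) * 3 + a] -= fa;
        }
      }
      // Coulomb with reaction field among charged sites
      for (int si = 0; si < ns; ++si) {
        double qi = S.sq[si];
        if (qi == 0) continue;
        const double *pi_ = &S.sp[(i * ns + si) * 3];
        for (int sj = 0; sj < ns; ++sj) {
          double qj = S.sq[sj];
          if (qj == 0) continue;
          const double *pj_ = &S.sp[(j * ns + sj) * 3];
          double e[3], rr2 = 0;
          for (int a = 0; a < 3; ++a) {
            e[a] = pi_[a] - pj_[a] + sh[a];
            rr2 += e[a] * e[a];
          }
          double rr = std::sqrt(rr2), qq = 138.935458 * qi * qj;
          upair += qq * (1.0 / rr + S.krf * rr2 - S.crf);
          double fs = qq * (1.0 / (rr2 * rr) - 2.0 * S.krf);
          for (int a = 0; a < 3; ++a) {
            double fa = fs * e[a];
            pf[si * 3 + a] += fa;
            pf[(ns + sj) * 3 + a] -= fa;
          }
        }
      }
      // quintic switch on the molecule-pair interaction over [rsw, rc]:
      // keeps the Hamiltonian smooth as pairs cross the cutoff (the raw
      // molecule-based cutoff otherwise pumps heat into the system)
      double sw = 1.0, dsw = 0.0, rOO = std::sqrt(r2);
      if (rOO > S.rsw) {
        double x = (rOO - S.rsw) / (S.rc - S.rsw);
        sw = 1 + x * x * x * (-10 + x * (15 - 6 * x));
        dsw = x * x * (-30 + x * (60 - 30 * x)) / (S.rc - S.rsw);
      }
      S.epot += sw * upair;
      for (int s = 0; s < ns; ++s)
        for (int a = 0; a < 3; ++a) {
          sf[(i * ns + s) * 3 + a] += sw * pf[s * 3 + a];
          sf[(j * ns + s) * 3 + a] += sw * pf[(ns + s) * 3 + a];
        }
      if (dsw != 0.0)
        for (int a = 0; a < 3; ++a) {
          double fa = -upair * dsw * d[a] / rOO;
          sf[(i * ns) * 3 + a] += fa;
          sf[(j * ns) * 3 + a] -= fa;
        }
    }
  }
  // clamp site forces (start-up safety), then reduce to COM force and
  // body-frame torque
  for (int i = 0; i < n; ++i) {
    const double *A = &S.A[i * 9];
    for (int s = 0; s < ns; ++s) {
      double *f = &sf[(i * ns + s) * 3];
      if (fmax > 0) {
        double fn = std::sqrt(f[0] * f[0] + f[1] * f[1] + f[2] * f[2]);
        if (fn > fmax) { double sc = fmax / fn; f[0] *= sc; f[1] *= sc; f[2] *= sc; }
      }
      double rel[3];
      for (int a = 0; a < 3; ++a) {
        S.F[i * 3 + a] += f[a];
        rel[a] = S.sp[(i * ns + s) * 3 + a] - S.r[i * 3 + a];
      }
      double tl[3] = {rel[1] * f[2] - rel[2] * f[1],
                      rel[2] * f[0] - rel[0] * f[2],
                      rel[0] * f[1] - rel[1] * f[0]};
      for (int a = 0; a < 3; ++a)
        S.T[i * 3 + a] += A[0 * 3 + a] * tl[0] + A[1 * 3 + a] * tl[1] +
                          A[2 * 3 + a] * tl[2];
    }
  }
}

static inline double kinetic(const WaterSystem &S) {
  double K = 0;
  for (int i = 0; i < S.n; ++i) {
    const double *v = &S.v[i * 3];
    const double *L = &S.Lb[i * 3];
    K += 0.5 * S.M * (v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    K += 0.5 * (L[0] * L[0] / S.Ib[0] + L[1] * L[1] / S.Ib[1] +
                L[2] * L[2] / S.Ib[2]);
  }
  return K;
}

static void remove_drift(WaterSystem &S) {
  double p[3] = {0, 0, 0};
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) p[a] += S.M * S.v[i * 3 + a];
  for (int i = 0; i < S.n; ++i)
    for (int a = 0; a < 3; ++a) S.v[i * 3 + a] -= p[a] / (S.M * S.n);
}

// one CSVR rescale factor; Nf degrees of freedom, target temperature Tt
static double csvr_alpha(double K, int Nf, double Tt, double dt, double tau,
                         std::mt19937_64 &rng) {
  if (K <= 0) return 1.0;
  double Kbar = 0.5 * Nf * KB * Tt;
  double c = std::exp(-dt / tau);
  std::normal_distribution<double> nd(0.0, 1.0);
  std::gamma_distribution<double> gd((Nf - 1) / 2.0, 1.0);
  double R1 = nd(rng);
  double Ssum = 2.0 * gd(rng); // chi^2 with Nf-1 dof
  double a2 = c + (1 - c) * (Ssum + R1 * R1) * Kbar / (Nf * K) +
              2.0 * R1 * std::sqrt(c * (1 - c) * Kbar / (Nf * K));
  return std::sqrt(std::max(a2, 1e-12));
}

static void md_steps(WaterSystem &S, int nsteps, double dt, double Tt,
                     double tau, double fmax, std::mt19937_64 &rng,
                     NumericVector *comv, NumericVector *angv,
                     NumericVector *tser, NumericVector *eser,
                     int out_every, int nF, int *frame) {
  int n = S.n;
  int Nf = 6 * n - 3;
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      for (int a = 0; a < 3; ++a) {
        S.v[i * 3 + a] += 0.5 * dt * S.F[i * 3 + a] / S.M;
        S.Lb[i * 3 + a] += 0.5 * dt * S.T[i * 3 + a];
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int a = 0; a < 3; ++a) S.r[i * 3 + a] += dt * S.v[i * 3 + a];
      free_rotation(S, i, dt);
    }
    compute_forces(S, fmax);
    for (int i = 0; i < n; ++i) {
      for (int a = 0; a < 3; ++a) {
        S.v[i * 3 + a] += 0.5 * dt * S.F[i * 3 + a] / S.M;
        S.Lb[i * 3 + a] += 0.5 * dt * S.T[i * 3 + a];
      }
    }
    double K = kinetic(S);
    double al = csvr_alpha(K, Nf, Tt, dt, tau, rng);
    for (size_t k = 0; k < S.v.size(); ++k) { S.v[k] *= al; S.Lb[k] *= al; }
    if (step % 100 == 0) remove_drift(S);
    if (step % 500 == 0)
      for (int i = 0; i < n; ++i) gram_schmidt(&S.A[i * 9]);
    if (comv && (step + 1) % out_every == 0 && *frame < nF) {
      int f = (*frame)++;
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) {
          (*comv)[f + nF * (i + (size_t)n * a)] = S.v[i * 3 + a];
          (*angv)[f + nF * (i + (size_t)n * a)] = S.Lb[i * 3 + a] / S.Ib[a];
        }
      (*tser)[f] = kinetic(S) / (0.5 * Nf * KB);
      (*eser)[f] = S.epot;
    }
  }
}

// [[Rcpp::export(name = ".cpp_water_md")]]
List cpp_water_md(int n_mol, double box, double temperature, int seed,
                  double cutoff,
                  NumericVector site_masses, NumericMatrix site_local,
                  NumericVector site_charges, NumericVector principal_moments,
                  double sigma, double epsilon,
                  double dt_equil1, int n_equil1,
                  double dt, int n_equil2, int n_prod, int out_every,
                  double tau_equil, double tau_prod) {
  WaterSystem S;
  S.n = n_mol; S.box = box; S.rc = cutoff; S.rc2 = cutoff * cutoff;
  S.rsw = cutoff - 0.1;
  S.krf = 0.5 / (cutoff * cutoff * cutoff);
  S.crf = 1.5 / cutoff;
  S.sigma6 = std::pow(sigma, 6); S.eps4 = 4.0 * epsilon;
  S.ns = site_masses.size();
  S.sq.assign(site_charges.begin(), site_charges.end());
  S.sl.resize(S.ns * 3);
  for (int s = 0; s < S.ns; ++s)
    for (int a = 0; a < 3; ++a) S.sl[s * 3 + a] = site_local(s, a);
  S.M = 0; for (double m : site_masses) S.M += m;
  for (int a = 0; a < 3; ++a) S.Ib[a] = principal_moments[a];
  S.r.resize(n_mol * 3); S.v.resize(n_mol * 3);
  S.A.resize(n_mol * 9); S.Lb.resize(n_mol * 3);
  S.F.assign(n_mol * 3, 0.0); S.T.assign(n_mol * 3, 0.0);
  S.sp.resize((size_t)n_mol * S.ns * 3);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);

  // simple-cubic COM lattice, random orientations, Maxwell velocities
  int nside = (int)std::ceil(std::cbrt((double)n_mol));
  double a0 = box / nside;
  int k = 0;
  for (int ix = 0; ix < nside && k < n_mol; ++ix)
    for (int iy = 0; iy < nside && k < n_mol; ++iy)
      for (int iz = 0; iz < nside && k < n_mol; ++iz) {
        S.r[k * 3 + 0] = (ix + 0.5) * a0;
        S.r[k * 3 + 1] = (iy + 0.5) * a0;
        S.r[k * 3 + 2] = (iz + 0.5) * a0;
        // random rotation: start from identity, rotate by random angles
        double *A = &S.A[k * 9];
        for (int a = 0; a < 9; ++a) A[a] = (a % 4 == 0) ? 1.0 : 0.0;
        double Ltmp[3] = {0, 0, 0};
        for (int ax = 0; ax < 3; ++ax)
          rotate_body(A, Ltmp, ax, 2 * M_PI * (nd(rng)));
        gram_schmidt(A);
        double sv = std::sqrt(KB * temperature / S.M);
        for (int a = 0; a < 3; ++a) S.v[k * 3 + a] = sv * nd(rng);
        for (int a = 0; a < 3; ++a)
          S.Lb[k * 3 + a] = std::sqrt(KB * temperature * S.Ib[a]) * nd(rng);
        ++k;
      }
  remove_drift(S);
  compute_forces(S, 1e4);

  int nF = n_prod / out_every;
  NumericVector comv((size_t)nF * n_mol * 3), angv((size_t)nF * n_mol * 3);
  NumericVector tser(nF), eser(nF);
  int frame = 0;

  // stage 1: short-timestep start-up with clamped forces
  md_steps(S, n_equil1, dt_equil1, temperature, tau_equil, 1e4, rng,
           nullptr, nullptr, nullptr, nullptr, 1, 0, &frame);
  // stage 2: full-timestep equilibration
  md_steps(S, n_equil2, dt, temperature, tau_equil, -1, rng,
           nullptr, nullptr, nullptr, nullptr, 1, 0, &frame);
  // production with output
  md_steps(S, n_prod, dt, temperature, tau_prod, -1, rng,
           &comv, &angv, &tser, &eser, out_every, nF, &frame);

  comv.attr("dim") = IntegerVector::create(nF, n_mol, 3);
  angv.attr("dim") = IntegerVector::create(nF, n_mol, 3);

  // final site positions and velocities (v_site = v_com + w x r_rel, lab)
  NumericMatrix spos((size_t)n_mol * S.ns, 3), svel((size_t)n_mol * S.ns, 3);
  for (int i = 0; i < n_mol; ++i) {
    const double *A = &S.A[i * 9];
    double wb[3] = {S.Lb[i * 3 + 0] / S.Ib[0], S.Lb[i * 3 + 1] / S.Ib[1],
                    S.Lb[i * 3 + 2] / S.Ib[2]};
    double wl[3];
    for (int a = 0; a < 3; ++a)
      wl[a] = A[a * 3 + 0] * wb[0] + A[a * 3 + 1] * wb[1] + A[a * 3 + 2] * wb[2];
    for (int s = 0; s < S.ns; ++s) {
      double rel[3];
      for (int a = 0; a < 3; ++a) {
        double x = 0;
        for (int b = 0; b < 3; ++b) x += A[a * 3 + b] * S.sl[s * 3 + b];
        rel[a] = x;
        spos(i * S.ns + s, a) = S.r[i * 3 + a] + x;
      }
      double wxr[3] = {wl[1] * rel[2] - wl[2] * rel[1],
                       wl[2] * rel[0] - wl[0] * rel[2],
                       wl[0] * rel[1] - wl[1] * rel[0]};
      for (int a = 0; a < 3; ++a)
        svel(i * S.ns + s, a) = S.v[i * 3 + a] + wxr[a];
    }
  }
  return List::create(_["com_velocities"] = comv,
                      _["angular_velocities"] = angv,
                      _["temperature_series"] = tser,
                      _["potential_series"] = eser,
                      _["site_positions"] = spos,
                      _["site_velocities"] = svel,
                      _["n_frames"] = nF);
}

// [[Rcpp::export(name = ".cpp_softsphere_ld")]]
List cpp_softsphere_ld(int n, double box, double temperature, double gamma,
                       double mass, double sigma, double epsilon,
                       double dt, int n_equil, int n_prod, int out_every,
                       int seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> ud(0.0, 1.0);
  double rc = 2.5 * sigma, s12 = std::pow(sigma, 12);
  if (rc > box / 2) rc = box / 2;
  double rc2 = rc * rc;

  // random placement with a minimum-distance rejection
  std::vector<double> r(n * 3), v(n * 3), F(n * 3, 0.0);
  double dmin2 = 0.7225 * sigma * sigma; // (0.85 sigma)^2
  for (int i = 0; i < n; ++i) {
    bool ok = false;
    for (int tries = 0; tries < 2000 && !ok; ++tries) {
      for (int a = 0; a < 3; ++a) r[i * 3 + a] = ud(rng) * box;
      ok = true;
      for (int j = 0; j < i && ok; ++j) {
        double d2 = 0;
        for (int a = 0; a < 3; ++a) {
          double d = r[i * 3 + a] - r[j * 3 + a];
          d -= box * std::nearbyint(d / box);
          d2 += d * d;
        }
        if (d2 < dmin2) ok = false;
      }
    }
    if (!ok) stop("could not place particle %d without overlap; box too small", i + 1);
  }
  double sv = std::sqrt(KB * temperature / mass);
  for (int k = 0; k < 3 * n; ++k) v[k] = sv * nd(rng);

  auto forces = [&]() {
    std::fill(F.begin(), F.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d[3], r2 = 0;
        for (int a = 0; a < 3; ++a) {
          d[a] = r[i * 3 + a] - r[j * 3 + a];
          d[a] -= box * std::nearbyint(d[a] / box);
          r2 += d[a] * d[a];
        }
        if (r2 >= rc2) continue;
        double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
        double fs = 12.0 * epsilon * s12 * ir6 * ir6 * ir2;
        for (int a = 0; a < 3; ++a) {
          F[i * 3 + a] += fs * d[a];
          F[j * 3 + a] -= fs * d[a];
        }
      }
  };
  forces();
  double c1 = std::exp(-gamma * dt), c2 = sv * std::sqrt(1 - c1 * c1);

  int nF = n_prod / out_every;
  NumericVector pos((size_t)nF * n * 3), vel((size_t)nF * n * 3);
  int frame = 0;
  int total = n_equil + n_prod;
  for (int step = 0; step < total; ++step) {
    for (int k = 0; k < 3 * n; ++k) v[k] += 0.5 * dt * F[k] / mass;
    for (int k = 0; k < 3 * n; ++k) r[k] += 0.5 * dt * v[k];
    for (int k = 0; k < 3 * n; ++k) v[k] = c1 * v[k] + c2 * nd(rng);
    for (int k = 0; k < 3 * n; ++k) r[k] += 0.5 * dt * v[k];
    forces();
    for (int k = 0; k < 3 * n; ++k) v[k] += 0.5 * dt * F[k] / mass;
    if (step >= n_equil && (step - n_equil + 1) % out_every == 0 && frame < nF) {
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) {
          pos[frame + nF * (i + (size_t)n * a)] = r[i * 3 + a];
          vel[frame + nF * (i + (size_t)n * a)] = v[i * 3 + a];
        }
      ++frame;
    }
  }
  pos.attr("dim") = IntegerVector::create(nF, n, 3);
  vel.attr("dim") = IntegerVector::create(nF, n, 3);
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["n_frames"] = nF);
}

// k-th nearest-neighbor distances on a flat torus (period 2*pi per axis),
// Euclidean metric, brute force.  Used by the circular kNN entropy
// estimators; n up to ~2e4 is fine.
// [[Rcpp::export(name = ".cpp_knn_torus")]]
NumericVector cpp_knn_torus(NumericMatrix x, int k, double period) {
  int n = x.nrow(), d = x.ncol();
  if (k >= n) stop("k must be smaller than the sample size");
  NumericVector out(n);
  std::vector<double> dist(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) { dist[j] = R_PosInf; continue; }
      double s = 0;
      for (int a = 0; a < d; ++a) {
        double dd = std::fabs(x(i, a) - x(j, a));
        if (dd > period / 2) dd = period - dd;
        s += dd * dd;
      }
      dist[j] = s;
    }
    std::nth_element(dist.begin(), dist.begin() + (k - 1), dist.end());
    out[i] = std::sqrt(dist[k - 1]);
  }
  return out;
}
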