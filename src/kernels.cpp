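// Energy, analytic forces and time integration for the coarse-grained
// protein + nanotube model. Units: A, kcal/mol, amu, fs.
//
// The dynamic coordinate vector holds the CA sites (0..n_res-1) followed by
// the side-chain sites of non-glycine residues; peptide-group sites are
// derived midpoints whose nanotube forces are chain-ruled onto the flanking
// CA sites. The cylinder axis runs along z through (lx/2, ly/2) and is not
// replicated in the lateral periodic images.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double ACC_CONV = 4.184e-4;       // (kcal/mol/A)/amu -> A/fs^2
static const double R_KCAL = 1.98720425864083e-3;  // kcal/mol/K

struct Sys {
  int n_res, nsite;
  double hx, hy, hz;  // half box edges (cached for the minimum image)
  std::vector<int> sc_idx;          // dynamic index of residue's SC (CA index for Gly)
  std::vector<double> mass;
  double lx, ly, lz;
  // bonded
  double kb, b0, kth, th0, kgam, gam_phase; int gam_n;
  std::vector<double> ksc, d0;      // per residue (d0 = 0 -> no attachment term)
  // nonbonded
  std::vector<int> nb_i, nb_j;
  std::vector<double> nb_eps, nb_sig;
  double nb_cut_factor;
  // Go contacts
  std::vector<int> go_i, go_j;
  std::vector<double> go_r0, go_eps;
  // nanotube
  bool use_cnt; double R0, w_cnt;
  std::vector<int> cntS_idx; std::vector<double> cntS_eps, cntS_sig;
  std::vector<double> cntP_eps, cntP_sig;   // one per peptide group (n_res-1)
  // restraints
  std::vector<int> rs_i, rs_j;
  std::vector<double> rs_x0, rs_A, rs_sig;
  double rs_half, w_rest;
};

static Sys parse_sys(const List& s) {
  Sys y;
  y.n_res = as<int>(s["n_res"]); y.nsite = as<int>(s["nsite"]);
  y.sc_idx = as<std::vector<int>>(s["sc_idx"]);
  y.mass = as<std::vector<double>>(s["mass"]);
  NumericVector box = s["box"];
  y.lx = box[0]; y.ly = box[1]; y.lz = box[2];
  y.hx = 0.5 * y.lx; y.hy = 0.5 * y.ly; y.hz = 0.5 * y.lz;
  y.kb = as<double>(s["kb"]); y.b0 = as<double>(s["b0"]);
  y.kth = as<double>(s["kth"]); y.th0 = as<double>(s["th0"]);
  y.kgam = as<double>(s["kgam"]); y.gam_n = as<int>(s["gam_n"]);
  y.gam_phase = as<double>(s["gam_phase"]);
  y.ksc = as<std::vector<double>>(s["ksc"]);
  y.d0 = as<std::vector<double>>(s["d0"]);
  y.nb_i = as<std::vector<int>>(s["nb_i"]); y.nb_j = as<std::vector<int>>(s["nb_j"]);
  y.nb_eps = as<std::vector<double>>(s["nb_eps"]);
  y.nb_sig = as<std::vector<double>>(s["nb_sig"]);
  y.nb_cut_factor = as<double>(s["nb_cut_factor"]);
  y.go_i = as<std::vector<int>>(s["go_i"]); y.go_j = as<std::vector<int>>(s["go_j"]);
  y.go_r0 = as<std::vector<double>>(s["go_r0"]);
  y.go_eps = as<std::vector<double>>(s["go_eps"]);
  y.use_cnt = as<bool>(s["use_cnt"]);
  y.R0 = as<double>(s["R0"]); y.w_cnt = as<double>(s["w_cnt"]);
  y.cntS_idx = as<std::vector<int>>(s["cntS_idx"]);
  y.cntS_eps = as<std::vector<double>>(s["cntS_eps"]);
  y.cntS_sig = as<std::vector<double>>(s["cntS_sig"]);
  y.cntP_eps = as<std::vector<double>>(s["cntP_eps"]);
  y.cntP_sig = as<std::vector<double>>(s["cntP_sig"]);
  y.rs_i = as<std::vector<int>>(s["rs_i"]); y.rs_j = as<std::vector<int>>(s["rs_j"]);
  y.rs_x0 = as<std::vector<double>>(s["rs_x0"]);
  y.rs_A = as<std::vector<double>>(s["rs_A"]);
  y.rs_sig = as<std::vector<double>>(s["rs_sig"]);
  y.rs_half = as<double>(s["rs_half"]); y.w_rest = as<double>(s["w_rest"]);
  return y;
}

struct EnergyOut {
  double u_bond = 0, u_angle = 0, u_dihedral = 0, u_scatt = 0, u_nb = 0,
         u_go = 0, u_cnt = 0, u_rest = 0;
  int status = 0, bad_site = -1;   // status 1: site at/inside tube surface
  double u_protein() const {
    return u_bond + u_angle + u_dihedral + u_scatt + u_nb + u_go;
  }
};

static inline void minimg(double& dx, double& dy, double& dz, const Sys& s) {
  // single-image fold (valid while displacements stay below 1.5 box edges;
  // general wrap for arbitrary offsets)
  if (dx > s.hx || dx < -s.hx) dx -= s.lx * std::round(dx / s.lx);
  if (dy > s.hy || dy < -s.hy) dy -= s.ly * std::round(dy / s.ly);
  if (dz > s.hz || dz < -s.hz) dz -= s.lz * std::round(dz / s.lz);
}

// xoshiro256++ with Box-Muller normals: fast thermostat noise, seeded from
// R's RNG stream so runs stay reproducible under set.seed().
struct FastNormal {
  uint64_t s[4];
  double spare; bool has_spare = false;
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_r() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next_u64();
  }
  uint64_t next_u64() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double next_uniform() {  // in (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = next_uniform(), u2 = next_uniform();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
};

// Kihara term in the surface distance d = r - R0; optional linear
// extrapolation below dcap keeps the minimizer's objective finite.
static inline double kihara_ud(double d, double eps, double sig, bool soft,
                               double* dudd) {
  double dcap = 0.35 * sig;
  if (soft && d < dcap) {
    double s6 = std::pow(sig / dcap, 6.0);
    double u0 = 4.0 * eps * (s6 * s6 - s6);
    double g0 = (24.0 * eps / dcap) * (s6 - 2.0 * s6 * s6);
    *dudd = g0;
    return u0 + g0 * (d - dcap);
  }
  double x = (sig * sig) / (d * d);
  double s6 = x * x * x;
  *dudd = (24.0 * eps / d) * (s6 - 2.0 * s6 * s6);
  return 4.0 * eps * (s6 * s6 - s6);
}

// Full energy + forces. pos/frc are nsite x 3 (column-major R matrices).
// `active` optionally restricts the nonbonded loop to a Verlet neighbor
// list (indices into the full pair arrays); all listed pairs within the
// cutoff are evaluated, so energies are unchanged by the list.
static EnergyOut energy_forces(const double* pos, double* frc, const Sys& s,
                               bool soft_wall,
                               const std::vector<int>* active = nullptr) {
  EnergyOut e;
  const int N = s.nsite, n = s.n_res;
  auto X = [&](int i) { return pos[i]; };
  auto Y = [&](int i) { return pos[i + N]; };
  auto Z = [&](int i) { return pos[i + 2 * N]; };
  auto addf = [&](int i, double fx, double fy, double fz) {
    frc[i] += fx; frc[i + N] += fy; frc[i + 2 * N] += fz;
  };
  for (int i = 0; i < 3 * N; ++i) frc[i] = 0.0;

  // virtual bonds CA(i)-CA(i+1)
  for (int i = 0; i + 1 < n; ++i) {
    double dx = X(i + 1) - X(i), dy = Y(i + 1) - Y(i), dz = Z(i + 1) - Z(i);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dev = r - s.b0;
    e.u_bond += s.kb * dev * dev;
    double g = 2.0 * s.kb * dev / r;  // dU/dr / r
    addf(i, g * dx, g * dy, g * dz);
    addf(i + 1, -g * dx, -g * dy, -g * dz);
  }

  // virtual-bond angles
  for (int i = 0; i + 2 < n; ++i) {
    double ux = X(i) - X(i + 1), uy = Y(i) - Y(i + 1), uz = Z(i) - Z(i + 1);
    double wx = X(i + 2) - X(i + 1), wy = Y(i + 2) - Y(i + 1), wz = Z(i + 2) - Z(i + 1);
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lw = std::sqrt(wx * wx + wy * wy + wz * wz);
    double ct = (ux * wx + uy * wy + uz * wz) / (lu * lw);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dev = th - s.th0;
    e.u_angle += s.kth * dev * dev;
    double st = std::sqrt(std::max(1e-16, 1.0 - ct * ct));
    double dUdth = 2.0 * s.kth * dev;
    // d(theta)/d(a) etc.
    double ax = (ct * ux / lu - wx / lw) / (lu * st);
    double ay = (ct * uy / lu - wy / lw) / (lu * st);
    double az = (ct * uz / lu - wz / lw) / (lu * st);
    double cx = (ct * wx / lw - ux / lu) / (lw * st);
    double cy = (ct * wy / lw - uy / lu) / (lw * st);
    double cz = (ct * wz / lw - uz / lu) / (lw * st);
    addf(i, -dUdth * ax, -dUdth * ay, -dUdth * az);
    addf(i + 2, -dUdth * cx, -dUdth * cy, -dUdth * cz);
    addf(i + 1, dUdth * (ax + cx), dUdth * (ay + cy), dUdth * (az + cz));
  }

  // virtual-bond dihedrals: U = kgam * (1 + cos(n*phi - phase))
  for (int i = 0; i + 3 < n; ++i) {
    double b1x = X(i + 1) - X(i), b1y = Y(i + 1) - Y(i), b1z = Z(i + 1) - Z(i);
    double b2x = X(i + 2) - X(i + 1), b2y = Y(i + 2) - Y(i + 1), b2z = Z(i + 2) - Z(i + 1);
    double b3x = X(i + 3) - X(i + 2), b3y = Y(i + 3) - Y(i + 2), b3z = Z(i + 3) - Z(i + 2);
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
           n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
           n2z = b2x * b3y - b2y * b3x;
    double l1s = n1x * n1x + n1y * n1y + n1z * n1z;
    double l2s = n2x * n2x + n2y * n2y + n2z * n2z;
    double lb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (l1s < 1e-14 || l2s < 1e-14) continue;  // collinear: term undefined
    double mx = n1y * n2z - n1z * n2y, my = n1z * n2x - n1x * n2z,
           mz = n1x * n2y - n1y * n2x;
    double ssin = (mx * b2x + my * b2y + mz * b2z) / lb2;
    double scos = n1x * n2x + n1y * n2y + n1z * n2z;
    double phi = std::atan2(ssin, scos);
    e.u_dihedral += s.kgam * (1.0 + std::cos(s.gam_n * phi - s.gam_phase));
    double dUdphi = -s.kgam * s.gam_n * std::sin(s.gam_n * phi - s.gam_phase);
    double fax = -lb2 / l1s * n1x, fay = -lb2 / l1s * n1y, faz = -lb2 / l1s * n1z;
    double fdx = lb2 / l2s * n2x, fdy = lb2 / l2s * n2y, fdz = lb2 / l2s * n2z;
    double p = (b1x * b2x + b1y * b2y + b1z * b2z) / (lb2 * lb2);
    double q = (b3x * b2x + b3y * b2y + b3z * b2z) / (lb2 * lb2);
    double fbx = -(1.0 + p) * fax + q * fdx;
    double fby = -(1.0 + p) * fay + q * fdy;
    double fbz = -(1.0 + p) * faz + q * fdz;
    double fcx = p * fax - (1.0 + q) * fdx;
    double fcy = p * fay - (1.0 + q) * fdy;
    double fcz = p * faz - (1.0 + q) * fdz;
    addf(i, -dUdphi * fax, -dUdphi * fay, -dUdphi * faz);
    addf(i + 1, -dUdphi * fbx, -dUdphi * fby, -dUdphi * fbz);
    addf(i + 2, -dUdphi * fcx, -dUdphi * fcy, -dUdphi * fcz);
    addf(i + 3, -dUdphi * fdx, -dUdphi * fdy, -dUdphi * fdz);
  }

  // side-chain attachment
  for (int i = 0; i < n; ++i) {
    int j = s.sc_idx[i];
    if (j == i || s.d0[i] <= 0.0) continue;
    double dx = X(j) - X(i), dy = Y(j) - Y(i), dz = Z(j) - Z(i);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dev = r - s.d0[i];
    e.u_scatt += s.ksc[i] * dev * dev;
    double g = 2.0 * s.ksc[i] * dev / r;
    addf(i, g * dx, g * dy, g * dz);
    addf(j, -g * dx, -g * dy, -g * dz);
  }

  // nonbonded truncated-shifted LJ
  size_t n_nb = active ? active->size() : s.nb_i.size();
  for (size_t kk = 0; kk < n_nb; ++kk) {
    size_t k = active ? (size_t)(*active)[kk] : kk;
    int i = s.nb_i[k], j = s.nb_j[k];
    double dx = X(j) - X(i), dy = Y(j) - Y(i), dz = Z(j) - Z(i);
    minimg(dx, dy, dz, s);
    double r2 = dx * dx + dy * dy + dz * dz;
    double rc = s.nb_cut_factor * s.nb_sig[k];
    if (r2 >= rc * rc) continue;
    double r = std::sqrt(r2);
    double xx = (s.nb_sig[k] * s.nb_sig[k]) / r2;
    double s6 = xx * xx * xx;
    double cf2 = 1.0 / (s.nb_cut_factor * s.nb_cut_factor);
    double c6 = cf2 * cf2 * cf2;
    double ushift = 4.0 * s.nb_eps[k] * (c6 * c6 - c6);
    e.u_nb += 4.0 * s.nb_eps[k] * (s6 * s6 - s6) - ushift;
    double dudr = (24.0 * s.nb_eps[k] / r) * (s6 - 2.0 * s6 * s6);
    double g = -dudr / r;  // force on j along +d
    addf(j, g * dx, g * dy, g * dz);
    addf(i, -g * dx, -g * dy, -g * dz);
  }

  // Go native contacts: U = eps[(r0/r)^12 - 2 (r0/r)^6]
  for (size_t k = 0; k < s.go_i.size(); ++k) {
    int i = s.go_i[k], j = s.go_j[k];
    double dx = X(j) - X(i), dy = Y(j) - Y(i), dz = Z(j) - Z(i);
    minimg(dx, dy, dz, s);
    double r2g = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2g);
    double xg = (s.go_r0[k] * s.go_r0[k]) / r2g;
    double s6 = xg * xg * xg;
    e.u_go += s.go_eps[k] * (s6 * s6 - 2.0 * s6);
    double dudr = (12.0 * s.go_eps[k] / r) * (s6 - s6 * s6);
    double g = -dudr / r;
    addf(j, g * dx, g * dy, g * dz);
    addf(i, -g * dx, -g * dy, -g * dz);
  }

  // nanotube: side-chain centers + derived peptide midpoints
  if (s.use_cnt) {
    auto cnt_site = [&](double px, double py, double eps, double sig,
                        double* fx, double* fy) -> double {
      double dx = px - s.lx / 2.0, dy = py - s.ly / 2.0;
      dx -= s.lx * std::round(dx / s.lx);
      dy -= s.ly * std::round(dy / s.ly);
      double r = std::sqrt(dx * dx + dy * dy);
      double d = r - s.R0;
      if (!soft_wall && d <= 0.0) { e.status = 1; return 0.0; }
      double dudd; double u = kihara_ud(d, eps, sig, soft_wall, &dudd);
      double g = (r > 1e-9) ? -dudd / r : 0.0;
      *fx = g * dx; *fy = g * dy;
      return u;
    };
    for (size_t k = 0; k < s.cntS_idx.size() && e.status == 0; ++k) {
      int i = s.cntS_idx[k];
      double fx, fy;
      double u = cnt_site(X(i), Y(i), s.cntS_eps[k], s.cntS_sig[k], &fx, &fy);
      if (e.status) { e.bad_site = i; break; }
      e.u_cnt += u;
      addf(i, s.w_cnt * fx, s.w_cnt * fy, 0.0);
    }
    for (int i = 0; i + 1 < n && e.status == 0; ++i) {
      double px = 0.5 * (X(i) + X(i + 1)), py = 0.5 * (Y(i) + Y(i + 1));
      double fx, fy;
      double u = cnt_site(px, py, s.cntP_eps[i], s.cntP_sig[i], &fx, &fy);
      if (e.status) { e.bad_site = i; break; }
      e.u_cnt += u;
      addf(i, 0.5 * s.w_cnt * fx, 0.5 * s.w_cnt * fy, 0.0);
      addf(i + 1, 0.5 * s.w_cnt * fx, 0.5 * s.w_cnt * fy, 0.0);
    }
  }

  // flat-bottom Lorentzian restraints on CA pairs
  for (size_t k = 0; k < s.rs_i.size(); ++k) {
    int i = s.rs_i[k], j = s.rs_j[k];
    double dx = X(j) - X(i), dy = Y(j) - Y(i), dz = Z(j) - Z(i);
    minimg(dx, dy, dz, s);
    double x = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d;
    if (x <= s.rs_x0[k] - s.rs_half) d = x - s.rs_x0[k] + s.rs_half;
    else if (x >= s.rs_x0[k] + s.rs_half) d = x - s.rs_x0[k] - s.rs_half;
    else continue;
    double d2 = d * d, d4 = d2 * d2;
    double den = d4 + s.rs_sig[k];
    e.u_rest += s.rs_A[k] * d4 / den;
    double dudx = 4.0 * s.rs_A[k] * d * d2 * s.rs_sig[k] / (den * den);
    double g = -s.w_rest * dudx / x;
    addf(j, g * dx, g * dy, g * dz);
    addf(i, -g * dx, -g * dy, -g * dz);
  }
  return e;
}

static List energy_list(const EnergyOut& e, const Sys& s) {
  double u_prot = e.u_protein();
  double u_tot = u_prot + s.w_cnt * e.u_cnt + s.w_rest * e.u_rest;
  return List::create(
    _["u_bond"] = e.u_bond, _["u_angle"] = e.u_angle,
    _["u_dihedral"] = e.u_dihedral, _["u_sc_attach"] = e.u_scatt,
    _["u_nonbonded"] = e.u_nb, _["u_go"] = e.u_go,
    _["u_protein"] = u_prot, _["u_cnt_total"] = e.u_cnt,
    _["u_restraint"] = e.u_rest, _["u_total"] = u_tot,
    _["status"] = e.status, _["bad_site"] = e.bad_site + 1);
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, List sys, bool soft_wall = false) {
  Sys s = parse_sys(sys);
  NumericMatrix frc(s.nsite, 3);
  EnergyOut e = energy_forces(REAL(pos), REAL(frc), s, soft_wall);
  List out = energy_list(e, s);
  out["forces"] = frc;
  return out;
}

// ---------------------------------------------------------------------------
// Integrators. thermostat: 0 none (NVE), 1 Berendsen, 2 Langevin (BAOAB),
// 3 Nose-Hoover (single chain). Langevin uses R's RNG.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, List sys, double dt,
                int nsteps, int thermostat, double T_set, double tau_fs,
                NumericVector gamma_fs, double Q_fs, double Nf,
                int sample_every, int traj_every, double xi0, double eta0) {
  Sys s = parse_sys(sys);
  const int N = s.nsite;
  NumericMatrix pos(clone(pos0)), vel(clone(vel0)), frc(N, 3);
  double* P = REAL(pos); double* V = REAL(vel); double* F = REAL(frc);

  double xi = xi0, eta = eta0;
  FastNormal rng;
  std::vector<double> oc1(N), osd(N);   // per-site O-step factors (constant)
  if (thermostat == 2) {
    rng.seed_from_r();
    for (int i = 0; i < N; ++i) {
      oc1[i] = std::exp(-gamma_fs[i] * dt);
      osd[i] = std::sqrt((1.0 - oc1[i] * oc1[i]) * R_KCAL * T_set * ACC_CONV /
                         s.mass[i]);
    }
  }
  auto ekin = [&]() {
    double k = 0;
    for (int i = 0; i < N; ++i)
      k += s.mass[i] * (V[i] * V[i] + V[i + N] * V[i + N] +
                        V[i + 2 * N] * V[i + 2 * N]);
    return 0.5 * k / ACC_CONV;
  };

  // Verlet neighbor list for the nonbonded pairs, refreshed periodically
  const double skin = 2.0;
  const int refresh = 20;
  std::vector<int> active;
  auto rebuild = [&]() {
    active.clear();
    for (size_t k = 0; k < s.nb_i.size(); ++k) {
      int i = s.nb_i[k], j = s.nb_j[k];
      double dx = P[j] - P[i], dy = P[j + N] - P[i + N],
             dz = P[j + 2 * N] - P[i + 2 * N];
      minimg(dx, dy, dz, s);
      double rl = s.nb_cut_factor * s.nb_sig[k] + skin;
      if (dx * dx + dy * dy + dz * dz < rl * rl) active.push_back((int)k);
    }
  };
  rebuild();
  EnergyOut e = energy_forces(P, F, s, false, &active);
  if (e.status) stop("site at or inside the tube surface at start (site %d)",
                     e.bad_site + 1);

  int nsamp = nsteps / std::max(1, sample_every) + 1;
  NumericMatrix samples(nsamp, 10);
  int ntraj = (traj_every > 0) ? nsteps / traj_every + 1 : 0;
  NumericVector traj(ntraj > 0 ? (R_xlen_t)ntraj * N * 3 : 0);
  int isamp = 0, itraj = 0;

  auto record = [&](int step) {
    if (step % std::max(1, sample_every) == 0 && isamp < nsamp) {
      double K = ekin();
      double u_prot = e.u_protein();
      double u_tot = u_prot + s.w_cnt * e.u_cnt + s.w_rest * e.u_rest;
      double cons = u_tot + K;
      if (thermostat == 3)
        cons += 0.5 * Q_fs * xi * xi + Nf * R_KCAL * T_set * eta;
      samples(isamp, 0) = step;
      samples(isamp, 1) = step * dt;
      samples(isamp, 2) = u_prot;
      samples(isamp, 3) = e.u_cnt;
      samples(isamp, 4) = e.u_rest;
      samples(isamp, 5) = u_tot;
      samples(isamp, 6) = K;
      samples(isamp, 7) = u_tot + K;
      samples(isamp, 8) = 2.0 * K / (Nf * R_KCAL);
      samples(isamp, 9) = cons;
      ++isamp;
    }
    if (traj_every > 0 && step % traj_every == 0 && itraj < ntraj) {
      for (int i = 0; i < 3 * N; ++i)
        traj[(R_xlen_t)itraj * N * 3 + i] = P[i];
      ++itraj;
    }
  };
  record(0);

  const double half = 0.5 * dt;
  int status = 0, bad_site = -1, bad_step = -1;

  for (int step = 1; step <= nsteps; ++step) {
    if (step % refresh == 0) rebuild();
    if (thermostat == 3) {  // NH first half: xi update then velocity scale
      double K = ekin();
      xi += half * (2.0 * K - Nf * R_KCAL * T_set) / Q_fs;
      double sc = std::exp(-xi * half);
      for (int i = 0; i < 3 * N; ++i) V[i] *= sc;
      eta += xi * half;
    }

    if (thermostat == 2) {  // BAOAB
      for (int i = 0; i < N; ++i) {
        double am = ACC_CONV / s.mass[i];
        V[i] += half * F[i] * am;
        V[i + N] += half * F[i + N] * am;
        V[i + 2 * N] += half * F[i + 2 * N] * am;
      }
      for (int i = 0; i < 3 * N; ++i) P[i] += half * V[i];
      for (int i = 0; i < N; ++i) {
        V[i] = oc1[i] * V[i] + osd[i] * rng.next();
        V[i + N] = oc1[i] * V[i + N] + osd[i] * rng.next();
        V[i + 2 * N] = oc1[i] * V[i + 2 * N] + osd[i] * rng.next();
      }
      for (int i = 0; i < 3 * N; ++i) P[i] += half * V[i];
      e = energy_forces(P, F, s, false, &active);
      if (e.status) { status = 1; bad_site = e.bad_site; bad_step = step; break; }
      for (int i = 0; i < N; ++i) {
        double am = ACC_CONV / s.mass[i];
        V[i] += half * F[i] * am;
        V[i + N] += half * F[i + N] * am;
        V[i + 2 * N] += half * F[i + 2 * N] * am;
      }
    } else {  // velocity Verlet core (NVE / Berendsen / NH)
      for (int i = 0; i < N; ++i) {
        double am = ACC_CONV / s.mass[i];
        V[i] += half * F[i] * am;
        V[i + N] += half * F[i + N] * am;
        V[i + 2 * N] += half * F[i + 2 * N] * am;
      }
      for (int i = 0; i < 3 * N; ++i) P[i] += dt * V[i];
      e = energy_forces(P, F, s, false, &active);
      if (e.status) { status = 1; bad_site = e.bad_site; bad_step = step; break; }
      for (int i = 0; i < N; ++i) {
        double am = ACC_CONV / s.mass[i];
        V[i] += half * F[i] * am;
        V[i + N] += half * F[i + N] * am;
        V[i + 2 * N] += half * F[i + 2 * N] * am;
      }
    }

    if (thermostat == 1) {  // Berendsen weak-coupling rescale
      double K = ekin();
      double Ti = 2.0 * K / (Nf * R_KCAL);
      if (Ti > 0) {
        double lam = std::sqrt(1.0 + (dt / tau_fs) * (T_set / Ti - 1.0));
        for (int i = 0; i < 3 * N; ++i) V[i] *= lam;
      }
    } else if (thermostat == 3) {  // NH second half
      double sc_v = std::exp(-xi * half);
      for (int i = 0; i < 3 * N; ++i) V[i] *= sc_v;
      eta += xi * half;
      double K = ekin();
      xi += half * (2.0 * K - Nf * R_KCAL * T_set) / Q_fs;
    }

    record(step);
  }

  colnames(samples) = CharacterVector::create(
    "step", "time_fs", "u_protein", "u_cnt", "u_restraint", "u_pot",
    "e_kin", "e_tot", "T_inst", "conserved");
  List out = List::create(
    _["positions"] = pos, _["velocities"] = vel,
    _["samples"] = samples, _["xi"] = xi, _["eta"] = eta,
    _["status"] = status, _["bad_site"] = bad_site + 1,
    _["bad_step"] = bad_step, _["n_samples"] = isamp);
  if (ntraj > 0) {
    traj.attr("dim") = IntegerVector::create(N, 3, ntraj);
    out["trajectory"] = traj;
    out["n_traj"] = itraj;
  }
  return out;
}
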