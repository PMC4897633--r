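// Coarse peptide geometry and the replica-averaged restrained Monte Carlo
// sampler. Five sites per residue (N, CA, C, O, SC); torsions in degrees;
// coordinates in Angstrom; energies in kJ/mol.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;
static const double KB  = 0.0083144621; // kJ/mol/K

// fixed internal geometry (trans peptide, omega = 180)
static const double B_NCA  = 1.458, B_CAC = 1.525, B_CN = 1.329, B_CO = 1.231;
static const double A_NCAC = 111.2, A_CACN = 116.2, A_CNCA = 121.7,
                    A_CACO = 120.8, A_NCASC = 110.5;
static const double T_SC = -122.0; // improper C(i)-N(i)-CA(i)-SC(i), L-chirality

static inline double wrap180(double x) {
  return x - 360.0 * std::floor(x / 360.0 + 0.5);
}

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void unit3(double* a) {
  double n = std::sqrt(dot3(a, a));
  a[0] /= n; a[1] /= n; a[2] /= n;
}

// dihedral angle a-b-c-d in degrees, IUPAC sign convention
static double dihedral4(const double* a, const double* b, const double* c,
                        const double* d) {
  double b1[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double b2[3] = { c[0] - b[0], c[1] - b[1], c[2] - b[2] };
  double b3[3] = { d[0] - c[0], d[1] - c[1], d[2] - c[2] };
  double n1[3], n2[3], b2u[3] = { b2[0], b2[1], b2[2] }, m1[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  unit3(b2u);
  cross3(n1, b2u, m1);
  return std::atan2(dot3(m1, n2), dot3(n1, n2)) / DEG;
}

// place D given A, B, C: |CD| = r, angle(B,C,D) = theta, dihedral(A,B,C,D) = chi
static void nerf(const double* A, const double* B, const double* C, double r,
                 double theta_deg, double chi_deg, double* D) {
  double th = theta_deg * DEG, ch = chi_deg * DEG;
  double bc[3] = { C[0] - B[0], C[1] - B[1], C[2] - B[2] };
  unit3(bc);
  double ab[3] = { B[0] - A[0], B[1] - A[1], B[2] - A[2] };
  double n[3];
  cross3(ab, bc, n);
  unit3(n);
  double m[3];
  cross3(n, bc, m);
  double d2[3] = { -r * std::cos(th), r * std::sin(th) * std::cos(ch),
                   -r * std::sin(th) * std::sin(ch) };
  for (int k = 0; k < 3; ++k)
    D[k] = C[k] + d2[0] * bc[k] + d2[1] * m[k] + d2[2] * n[k];
}

// atom index helpers: residue i occupies slots 5i .. 5i+4 = N CA C O SC
static inline double* at(double* X, int i, int s) { return X + 3 * (5 * i + s); }
static inline const double* atc(const double* X, int i, int s) {
  return X + 3 * (5 * i + s);
}

// build (or rebuild from residue `start`) the chain into X (length 15n)
static void build_chain(const double* phi, const double* psi,
                        const double* scd, int n, double* X, int start = 0) {
  double C0[3] = { B_CN * std::cos(A_CNCA * DEG), B_CN * std::sin(A_CNCA * DEG),
                   0.0 };
  if (start == 0) {
    double* N = at(X, 0, 0);
    N[0] = N[1] = N[2] = 0.0;
    double* CA = at(X, 0, 1);
    CA[0] = B_NCA; CA[1] = CA[2] = 0.0;
  }
  for (int i = start; i < n; ++i) {
    const double* prevC = (i == 0) ? C0 : atc(X, i - 1, 2);
    const double* N = atc(X, i, 0);
    const double* CA = atc(X, i, 1);
    double* C = at(X, i, 2);
    nerf(prevC, N, CA, B_CAC, A_NCAC, phi[i], C);
    nerf(N, CA, C, B_CO, A_CACO, psi[i] + 180.0, at(X, i, 3));
    if (scd[i] > 0)
      nerf(C, N, CA, scd[i], A_NCASC, T_SC, at(X, i, 4));
    else
      std::memcpy(at(X, i, 4), CA, 3 * sizeof(double));
    if (i < n - 1) {
      double* Nn = at(X, i + 1, 0);
      nerf(N, CA, C, B_CN, A_CACN, psi[i], Nn);
      nerf(CA, C, Nn, B_NCA, A_CNCA, 180.0, at(X, i + 1, 1));
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_build_coords(NumericVector phi, NumericVector psi,
                               NumericVector sc_dist) {
  int n = phi.size();
  std::vector<double> X(15 * n);
  build_chain(phi.begin(), psi.begin(), sc_dist.begin(), n, X.data());
  NumericMatrix out(5 * n, 3);
  for (int a = 0; a < 5 * n; ++a)
    for (int k = 0; k < 3; ++k) out(a, k) = X[3 * a + k];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_build_coords_many(NumericMatrix phi, NumericMatrix psi,
                                    NumericVector sc_dist) {
  int F = phi.nrow(), n = phi.ncol();
  NumericVector out(5 * n * 3 * F);
  std::vector<double> X(15 * n), ph(n), ps(n);
  for (int f = 0; f < F; ++f) {
    for (int i = 0; i < n; ++i) { ph[i] = phi(f, i); ps[i] = psi(f, i); }
    build_chain(ph.data(), ps.data(), sc_dist.begin(), n, X.data());
    for (int a = 0; a < 5 * n; ++a)
      for (int k = 0; k < 3; ++k)
        out[f * 15 * n + k * 5 * n + a] = X[3 * a + k];
  }
  out.attr("dim") = IntegerVector::create(5 * n, 3, F);
  return out;
}

// [[Rcpp::export]]
List cpp_extract_torsions(NumericMatrix coords) {
  int n = coords.nrow() / 5;
  std::vector<double> X(15 * n);
  for (int a = 0; a < 5 * n; ++a)
    for (int k = 0; k < 3; ++k) X[3 * a + k] = coords(a, k);
  NumericVector phi(n), psi(n);
  phi[0] = NA_REAL; // gauge freedom: no C of residue 0
  for (int i = 0; i < n; ++i) {
    if (i > 0)
      phi[i] = dihedral4(atc(X.data(), i - 1, 2), atc(X.data(), i, 0),
                         atc(X.data(), i, 1), atc(X.data(), i, 2));
    if (i < n - 1)
      psi[i] = dihedral4(atc(X.data(), i, 0), atc(X.data(), i, 1),
                         atc(X.data(), i, 2), atc(X.data(), i + 1, 0));
    else
      psi[i] = wrap180(dihedral4(atc(X.data(), i, 0), atc(X.data(), i, 1),
                                 atc(X.data(), i, 2), atc(X.data(), i, 3)) -
                       180.0);
  }
  return List::create(_["phi"] = phi, _["psi"] = psi);
}

// [[Rcpp::export]]
double cpp_dihedral(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  return dihedral4(p1.begin(), p2.begin(), p3.begin(), p4.begin());
}

// ---------------------------------------------------------------- energy ----

struct EnergyPar {
  int n;
  std::vector<double> hd, ed; // per-residue basin depths (kJ/mol)
  double hw, ew;              // basin widths (deg)
  double hc_phi, hc_psi, ec_phi, ec_psi;
  double krep, w_t, w_rep;
  double cj, cw; // nearest-neighbour helix cooperativity (Ising-like)
  // repulsion pair list over CA/SC sites of residues |i-j| >= 2
  std::vector<int> pa, pb;     // flat atom indices (5i+1 or 5i+4)
  std::vector<int> ra, rb;     // residue index of each endpoint
  std::vector<char> sa, sb;    // endpoint is the SC site?
  std::vector<double> d0;      // contact distance per pair
};

static EnergyPar parse_energy(List par) {
  EnergyPar E;
  E.n = as<int>(par["n"]);
  E.hd = as<std::vector<double> >(par["helix_depth"]);
  E.ed = as<std::vector<double> >(par["ext_depth"]);
  E.hw = as<double>(par["helix_width"]);
  E.ew = as<double>(par["ext_width"]);
  NumericVector hc = par["helix_centre"], ec = par["ext_centre"];
  E.hc_phi = hc[0]; E.hc_psi = hc[1]; E.ec_phi = ec[0]; E.ec_psi = ec[1];
  E.krep = as<double>(par["repulsion_k"]);
  E.w_t = as<double>(par["w_torsion"]);
  E.w_rep = as<double>(par["w_repulsion"]);
  E.cj = as<double>(par["coop_j"]);
  E.cw = as<double>(par["coop_width"]);
  double car = as<double>(par["ca_radius"]);
  std::vector<double> scr = as<std::vector<double> >(par["sc_radius"]);
  for (int i = 0; i < E.n; ++i)
    for (int j = i + 2; j < E.n; ++j)
      for (int u = 0; u < 2; ++u) { // CA-CA and SC-SC pairs
        double ri = u ? scr[i] : car, rj = u ? scr[j] : car;
        if (ri <= 0 || rj <= 0) continue; // glycine SC sits on CA
        E.pa.push_back(5 * i + (u ? 4 : 1));
        E.pb.push_back(5 * j + (u ? 4 : 1));
        E.ra.push_back(i); E.rb.push_back(j);
        E.sa.push_back((char)u); E.sb.push_back((char)u);
        E.d0.push_back(ri + rj);
      }
  return E;
}

static inline double torsion_energy_res(const EnergyPar& E, int i, double phi,
                                        double psi) {
  double dh1 = wrap180(phi - E.hc_phi), dh2 = wrap180(psi - E.hc_psi);
  double de1 = wrap180(phi - E.ec_phi), de2 = wrap180(psi - E.ec_psi);
  double eh = E.hd[i] * std::exp(-(dh1 * dh1 + dh2 * dh2) / (2 * E.hw * E.hw));
  double ee = E.ed[i] * std::exp(-(de1 * de1 + de2 * de2) / (2 * E.ew * E.ew));
  return -(eh + ee);
}

static inline double pair_energy(const EnergyPar& E, const double* X,
                                 size_t p) {
  const double* a = X + 3 * E.pa[p];
  const double* b = X + 3 * E.pb[p];
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  double d2 = dx * dx + dy * dy + dz * dz, d0 = E.d0[p];
  if (d2 >= d0 * d0) return 0.0;
  double d = std::sqrt(d2);
  return E.krep * (d0 - d) * (d0 - d);
}

// helical-state weight used by the cooperativity term
static inline double coop_g(const EnergyPar& E, double phi, double psi) {
  double d1 = wrap180(phi + 57.0), d2 = wrap180(psi + 47.0);
  return std::exp(-(d1 * d1 + d2 * d2) / (2.0 * E.cw * E.cw));
}

static double repulsion_energy(const EnergyPar& E, const double* X) {
  double tot = 0.0;
  size_t np = E.pa.size();
  for (size_t p = 0; p < np; ++p) tot += pair_energy(E, X, p);
  return tot;
}

// [[Rcpp::export]]
List cpp_physical_energy(NumericVector phi, NumericVector psi,
                         NumericMatrix coords, List par) {
  EnergyPar E = parse_energy(par);
  int n = E.n;
  std::vector<double> X(15 * n);
  for (int a = 0; a < 5 * n; ++a)
    for (int k = 0; k < 3; ++k) X[3 * a + k] = coords(a, k);
  double et = 0.0;
  for (int i = 0; i < n; ++i) et += torsion_energy_res(E, i, phi[i], psi[i]);
  double ec = 0.0;
  for (int i = 0; i + 1 < n; ++i)
    ec -= E.cj * coop_g(E, phi[i], psi[i]) * coop_g(E, phi[i + 1], psi[i + 1]);
  double er = repulsion_energy(E, X.data());
  return List::create(_["torsion"] = E.w_t * et,
                      _["cooperativity"] = E.w_t * ec,
                      _["repulsion"] = E.w_rep * er,
                      _["total"] = E.w_t * (et + ec) + E.w_rep * er);
}

// ------------------------------------------------------------------ SASA ----

// Shrake-Rupley sphere sampling; pts = unit sphere points (m x 3)
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii, double probe,
                       NumericMatrix pts) {
  int n = coords.nrow(), m = pts.nrow();
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    if (radii[i] <= 0) { area[i] = 0.0; continue; }
    double ri = radii[i] + probe;
    int acc = 0;
    for (int p = 0; p < m; ++p) {
      double px = coords(i, 0) + ri * pts(p, 0);
      double py = coords(i, 1) + ri * pts(p, 1);
      double pz = coords(i, 2) + ri * pts(p, 2);
      bool free_pt = true;
      for (int j = 0; j < n && free_pt; ++j) {
        if (j == i || radii[j] <= 0) continue;
        double rj = radii[j] + probe;
        double dx = px - coords(j, 0), dy = py - coords(j, 1),
               dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) free_pt = false;
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / double(m);
  }
  return area;
}

// ------------------------------------------------------------------- RNG ----

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    // splitmix64 scramble so nearby seeds give unrelated streams
    s = seed + 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x1234567887654321ULL;
  }
  double unif() { // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return double((s * 0x2545F4914F6CDD1DULL) >> 11) *
           (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// -------------------------------------------------------------- sampler ----

struct Restraint {
  double k, s, eps_default;
  int M;
  std::vector<int> res, atom;          // per nucleus (0-based residue)
  std::vector<double> coil, dhel, target, eps;
  std::vector<std::vector<int> > by_res; // nucleus indices per residue
  bool active() const { return k > 0 && !res.empty(); }
};

static inline double helix_weight(double phi, double psi, double s) {
  double d1 = wrap180(phi + 57.0), d2 = wrap180(psi + 47.0);
  return std::exp(-(d1 * d1 + d2 * d2) / (2.0 * s * s));
}

static inline double pen_j(const Restraint& R, int j, double meanw) {
  double pred = R.coil[j] + meanw * R.dhel[j];
  double v = std::fabs(pred - R.target[j]) - R.eps[j];
  return v > 0 ? v * v : 0.0;
}

// [[Rcpp::export]]
List cpp_run_annealing(List arg) {
  int n = as<int>(arg["n_res"]);
  int M = as<int>(arg["n_replicas"]);
  std::vector<double> scd = as<std::vector<double> >(arg["sc_dist"]);
  EnergyPar E = parse_energy(arg["energy"]);

  // restraint block
  Restraint R;
  List rl = arg["restraint"];
  R.k = as<double>(rl["k"]);
  R.s = as<double>(rl["s"]);
  R.M = M;
  if (R.k > 0) {
    R.res = as<std::vector<int> >(rl["res"]);
    R.atom = as<std::vector<int> >(rl["atom"]);
    R.coil = as<std::vector<double> >(rl["coil"]);
    R.dhel = as<std::vector<double> >(rl["dhel"]);
    R.target = as<std::vector<double> >(rl["target"]);
    R.eps = as<std::vector<double> >(rl["eps"]);
  }
  R.by_res.assign(n, std::vector<int>());
  for (size_t j = 0; j < R.res.size(); ++j) R.by_res[R.res[j]].push_back((int)j);

  // schedule block
  List sch = arg["schedule"];
  int n_cycles = as<int>(sch["n_cycles"]);
  IntegerVector seg_sweeps = sch["seg_sweeps"];
  NumericMatrix seg_T = sch["seg_temp"]; // 4 x 2 (start, end)
  int discard_cycles = as<int>(sch["discard_cycles"]);
  int collect_every = as<int>(sch["collect_every"]);

  double width0 = as<double>(arg["move_width"]);
  bool adapt = as<bool>(arg["adapt"]);
  NumericVector seeds = arg["seeds"];

  std::vector<XRng> rng;
  for (int m = 0; m < M; ++m) rng.push_back(XRng((uint64_t)seeds[m]));

  // replica state
  std::vector<std::vector<double> > phi(M, std::vector<double>(n)),
      psi(M, std::vector<double>(n)), et(M, std::vector<double>(n)),
      w(M, std::vector<double>(n)), g(M, std::vector<double>(n));
  std::vector<std::vector<double> > X(M, std::vector<double>(15 * n));
  std::vector<double> erep(M), width(M, width0);

  bool has_init = arg.containsElementNamed("init_phi") &&
                  !Rf_isNull(arg["init_phi"]);
  NumericMatrix iphi, ipsi;
  if (has_init) { iphi = as<NumericMatrix>(arg["init_phi"]);
                  ipsi = as<NumericMatrix>(arg["init_psi"]); }
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) {
      if (has_init) { phi[m][i] = iphi(m, i); psi[m][i] = ipsi(m, i); }
      else { phi[m][i] = -180.0 + 360.0 * rng[m].unif();
             psi[m][i] = -180.0 + 360.0 * rng[m].unif(); }
    }
    build_chain(phi[m].data(), psi[m].data(), scd.data(), n, X[m].data());
    for (int i = 0; i < n; ++i) {
      et[m][i] = torsion_energy_res(E, i, phi[m][i], psi[m][i]);
      w[m][i] = helix_weight(phi[m][i], psi[m][i], R.s);
      g[m][i] = coop_g(E, phi[m][i], psi[m][i]);
    }
    erep[m] = repulsion_energy(E, X[m].data());
  }
  std::vector<double> meanw(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < M; ++m) meanw[i] += w[m][i];
    meanw[i] /= M;
  }
  std::vector<double> pen(R.res.size(), 0.0);
  double erest = 0.0;
  if (R.active()) {
    for (size_t j = 0; j < R.res.size(); ++j) {
      pen[j] = pen_j(R, j, meanw[R.res[j]]);
      erest += pen[j];
    }
    erest *= R.k;
  }

  // per-replica cached pair energies (pivot moves change only the pairs that
  // straddle the rotated suffix); straddling pairs are precomputed per pivot
  size_t np = E.pa.size();
  std::vector<std::vector<int> > cross_phi(n), cross_psi(n);
  for (int i = 0; i < n; ++i)
    for (size_t p = 0; p < np; ++p) {
      bool pa_rot = E.ra[p] > i || (E.ra[p] == i && E.sa[p]);
      bool pb_rot = E.rb[p] > i || (E.rb[p] == i && E.sb[p]);
      if (pa_rot != pb_rot) cross_phi[i].push_back((int)p);
      if ((E.ra[p] > i) != (E.rb[p] > i)) cross_psi[i].push_back((int)p);
    }
  std::vector<std::vector<double> > epair(M, std::vector<double>(np));
  for (int m = 0; m < M; ++m) {
    erep[m] = 0.0;
    for (size_t p = 0; p < np; ++p) {
      epair[m][p] = pair_energy(E, X[m].data(), p);
      erep[m] += epair[m][p];
    }
  }

  // output buffers
  std::vector<double> col_phi, col_psi, col_eph, col_erest;
  std::vector<int> col_rep, col_cyc;
  std::vector<double> tr_acc, tr_eph, tr_erest, tr_width;
  std::vector<int> tr_cyc, tr_rep;
  std::vector<double> undo(15 * n);
  std::vector<size_t> touched(np);
  std::vector<double> touched_e(np);

  for (int c = 0; c < n_cycles; ++c) {
    std::vector<long> prop(M, 0), acc(M, 0);
    for (int seg = 0; seg < 4; ++seg) {
      int S = seg_sweeps[seg];
      for (int t = 0; t < S; ++t) {
        double T = seg_T(seg, 0) +
                   (seg_T(seg, 1) - seg_T(seg, 0)) * (t + 1.0) / S;
        double beta = 1.0 / (KB * T);
        for (int m = 0; m < M; ++m) {
          double* Xm = X[m].data();
          for (int i = 0; i < n; ++i) {
            bool move_phi = rng[m].unif() < 0.5;
            double* ang = move_phi ? &phi[m][i] : &psi[m][i];
            double old = *ang;
            double newang = wrap180(old + width[m] * rng[m].norm());
            // pivot: rotate the suffix of the chain about the torsion axis
            const double* A = move_phi ? atc(Xm, i, 0) : atc(Xm, i, 1);
            const double* B = move_phi ? atc(Xm, i, 1) : atc(Xm, i, 2);
            double u[3] = { B[0] - A[0], B[1] - A[1], B[2] - A[2] };
            unit3(u);
            double th = -(newang - old) * DEG; // sign fixed by convention check
            double ct = std::cos(th), st = std::sin(th), oc = 1.0 - ct;
            double Rm[9] = {
              ct + u[0] * u[0] * oc, u[0] * u[1] * oc - u[2] * st,
              u[0] * u[2] * oc + u[1] * st,
              u[1] * u[0] * oc + u[2] * st, ct + u[1] * u[1] * oc,
              u[1] * u[2] * oc - u[0] * st,
              u[2] * u[0] * oc - u[1] * st, u[2] * u[1] * oc + u[0] * st,
              ct + u[2] * u[2] * oc };
            int a0 = move_phi ? (5 * i + 2) : (5 * (i + 1));
            int a1 = 5 * n; // suffix [a0, a1)
            int n_suffix = a1 - a0;
            // save + rotate suffix (and O_i for psi moves)
            if (n_suffix > 0)
              std::memcpy(undo.data(), Xm + 3 * a0,
                          3 * n_suffix * sizeof(double));
            double osave[3];
            double* Oi = Xm + 3 * (5 * i + 3);
            if (!move_phi) { osave[0] = Oi[0]; osave[1] = Oi[1];
                             osave[2] = Oi[2]; }
            for (int a = a0; a < a1; ++a) {
              double* pnt = Xm + 3 * a;
              double v0 = pnt[0] - B[0], v1 = pnt[1] - B[1],
                     v2 = pnt[2] - B[2];
              pnt[0] = B[0] + Rm[0] * v0 + Rm[1] * v1 + Rm[2] * v2;
              pnt[1] = B[1] + Rm[3] * v0 + Rm[4] * v1 + Rm[5] * v2;
              pnt[2] = B[2] + Rm[6] * v0 + Rm[7] * v1 + Rm[8] * v2;
            }
            if (!move_phi) {
              double v0 = Oi[0] - B[0], v1 = Oi[1] - B[1], v2 = Oi[2] - B[2];
              Oi[0] = B[0] + Rm[0] * v0 + Rm[1] * v1 + Rm[2] * v2;
              Oi[1] = B[1] + Rm[3] * v0 + Rm[4] * v1 + Rm[5] * v2;
              Oi[2] = B[2] + Rm[6] * v0 + Rm[7] * v1 + Rm[8] * v2;
            }
            // repulsion delta over straddling pairs only
            double dsum = 0.0;
            int ntouch = 0;
            if (E.w_rep != 0.0 && E.krep != 0.0) {
              const std::vector<int>& cl =
                  move_phi ? cross_phi[i] : cross_psi[i];
              for (size_t q = 0; q < cl.size(); ++q) {
                size_t p = (size_t)cl[q];
                double enew = pair_energy(E, Xm, p);
                dsum += enew - epair[m][p];
                touched[ntouch] = p;
                touched_e[ntouch] = enew;
                ++ntouch;
              }
            }
            *ang = newang;
            double et_new = torsion_energy_res(E, i, phi[m][i], psi[m][i]);
            double g_new = coop_g(E, phi[m][i], psi[m][i]);
            double gn = (i > 0 ? g[m][i - 1] : 0.0) +
                        (i + 1 < n ? g[m][i + 1] : 0.0);
            double dcoop = -E.cj * (g_new - g[m][i]) * gn;
            double dE = E.w_t * (et_new - et[m][i] + dcoop) + E.w_rep * dsum;
            double w_new = 0.0, meanw_new = 0.0;
            bool touch_r = R.active() && !R.by_res[i].empty();
            if (touch_r) {
              double dpen = 0.0;
              w_new = helix_weight(phi[m][i], psi[m][i], R.s);
              meanw_new = meanw[i] + (w_new - w[m][i]) / M;
              for (size_t q = 0; q < R.by_res[i].size(); ++q) {
                int j = R.by_res[i][q];
                dpen += pen_j(R, j, meanw_new) - pen[j];
              }
              dE += R.k * dpen;
            }
            ++prop[m];
            bool ok = dE <= 0.0 || rng[m].unif() < std::exp(-dE * beta);
            if (ok) {
              ++acc[m];
              et[m][i] = et_new;
              g[m][i] = g_new;
              erep[m] += dsum;
              for (int q = 0; q < ntouch; ++q)
                epair[m][touched[q]] = touched_e[q];
              if (touch_r) {
                w[m][i] = w_new;
                meanw[i] = meanw_new;
                for (size_t q = 0; q < R.by_res[i].size(); ++q) {
                  int j = R.by_res[i][q];
                  pen[j] = pen_j(R, j, meanw[i]);
                }
              }
            } else {
              *ang = old;
              if (n_suffix > 0)
                std::memcpy(Xm + 3 * a0, undo.data(),
                            3 * n_suffix * sizeof(double));
              if (!move_phi) { Oi[0] = osave[0]; Oi[1] = osave[1];
                               Oi[2] = osave[2]; }
            }
          }
        }
        if (seg == 0 && c >= discard_cycles && (t + 1) % collect_every == 0) {
          double er_now = 0.0;
          if (R.active()) {
            for (size_t j = 0; j < pen.size(); ++j) er_now += pen[j];
            er_now *= R.k;
          }
          for (int m = 0; m < M; ++m) {
            for (int i = 0; i < n; ++i) {
              col_phi.push_back(phi[m][i]);
              col_psi.push_back(psi[m][i]);
            }
            col_rep.push_back(m + 1);
            col_cyc.push_back(c + 1);
            double sumt = 0.0;
            for (int i = 0; i < n; ++i) sumt += et[m][i];
            for (int i = 0; i + 1 < n; ++i)
              sumt -= E.cj * g[m][i] * g[m][i + 1];
            col_eph.push_back(E.w_t * sumt + E.w_rep * erep[m]);
            col_erest.push_back(er_now);
          }
        }
      }
    }
    // per-cycle trace + width adaptation during the discard horizon
    double er_now = 0.0;
    if (R.active()) {
      for (size_t j = 0; j < pen.size(); ++j) er_now += pen[j];
      er_now *= R.k;
    }
    for (int m = 0; m < M; ++m) {
      double rate = prop[m] ? double(acc[m]) / double(prop[m]) : 0.0;
      double sumt = 0.0;
      for (int i = 0; i < n; ++i) sumt += et[m][i];
      for (int i = 0; i + 1 < n; ++i) sumt -= E.cj * g[m][i] * g[m][i + 1];
      tr_cyc.push_back(c + 1);
      tr_rep.push_back(m + 1);
      tr_acc.push_back(rate);
      tr_eph.push_back(E.w_t * sumt + E.w_rep * erep[m]);
      tr_erest.push_back(er_now);
      tr_width.push_back(width[m]);
      if (adapt && c < discard_cycles) {
        if (rate < 0.30) width[m] *= 0.8;
        else if (rate > 0.50) width[m] *= 1.25;
        if (width[m] < 2.0) width[m] = 2.0;
        if (width[m] > 60.0) width[m] = 60.0;
      }
    }
    // re-canonicalise coordinates from torsions once per cycle so pivot
    // round-off cannot accumulate over long runs
    for (int m = 0; m < M; ++m) {
      build_chain(phi[m].data(), psi[m].data(), scd.data(), n, X[m].data());
      erep[m] = 0.0;
      for (size_t p = 0; p < np; ++p) {
        epair[m][p] = pair_energy(E, X[m].data(), p);
        erep[m] += epair[m][p];
      }
    }
  }

  int F = (int)col_rep.size();
  NumericMatrix out_phi(F, n), out_psi(F, n);
  for (int f = 0; f < F; ++f)
    for (int i = 0; i < n; ++i) {
      out_phi(f, i) = col_phi[(size_t)f * n + i];
      out_psi(f, i) = col_psi[(size_t)f * n + i];
    }
  return List::create(
      _["phi"] = out_phi, _["psi"] = out_psi,
      _["replica"] = wrap(col_rep), _["cycle"] = wrap(col_cyc),
      _["e_physical"] = wrap(col_eph), _["e_restraint"] = wrap(col_erest),
      _["trace"] = List::create(
          _["cycle"] = wrap(tr_cyc), _["replica"] = wrap(tr_rep),
          _["acceptance"] = wrap(tr_acc), _["e_physical"] = wrap(tr_eph),
          _["e_restraint"] = wrap(tr_erest), _["move_width"] = wrap(tr_width)));
}
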