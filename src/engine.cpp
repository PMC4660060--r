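// Coarse-grained scoring + Monte Carlo / parallel-tempering engine.
//
// The energy model mirrors the exported R term functions exactly:
// connectivity (gap-only harmonic on sequence-adjacent surface distances),
// excluded volume (overlap harmonic on non-adjacent pairs), ambiguous
// cross-link upper-bound harmonics, localization boxes (copy-1 beads are
// mapped back through the inverse symmetry transform), subcomplex
// connectivity, and the optional tubulin-lattice terms used by docking.
// Incremental (single-bead / rigid-lattice) updates keep one MC step at
// O(N); full energies are recomputed at every exchange sweep so cached
// values cannot drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// xoshiro256++, seeded through splitmix64: fast and platform-deterministic
// (no dependence on the C++ stdlib distribution implementations).
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); } // [0,1)
  int randint(int n) { int k = (int)(unif() * n); return k >= n ? n - 1 : k; }
  // uniform in the unit ball, by rejection
  void ball(double *v) {
    double r2;
    do {
      v[0] = 2.0 * unif() - 1.0;
      v[1] = 2.0 * unif() - 1.0;
      v[2] = 2.0 * unif() - 1.0;
      r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    } while (r2 > 1.0 || r2 < 1e-12);
  }
};

// ------------------------------------------------------------- system ----
struct System {
  int n = 0;        // beads per copy
  int ncopy = 1;
  bool sym_on = false;
  std::vector<double> rad;
  std::vector<int> chain, comp;
  double R[9], t[3];           // copy0 -> copy1 (row major)
  // boxes (per copy-0 bead)
  std::vector<char> has_box;
  std::vector<double> blo, bhi; // 3 per bead
  double k_conn = 1, k_ev = 1, k_box = 1, k_sub = 1;
  // cross-links
  std::vector<int> xa, xb;
  std::vector<double> xbound, xk;
  std::vector<std::vector<int>> xl_of_bead;
  // subcomplex groups (component ids) and comp -> bead lists
  std::vector<std::vector<int>> groups;
  std::vector<std::vector<int>> comp_beads;
  std::vector<std::vector<int>> groups_of_comp;
  // lattice
  bool has_lat = false;
  int m = 0, nsub = 0;
  std::vector<double> L0, lrad;      // base coords (3 per bead), radii
  std::vector<int> lsub;
  double lat_ev_k = 1;
  std::vector<int> tc;               // complex bead per tubulin XL
  std::vector<std::vector<int>> tcand; // candidate lattice beads per record
  std::vector<double> tbound, tk;
  std::vector<std::vector<int>> txl_of_bead;
  double lat_max_trans = 2.0, lat_max_rot = 2.0; // A, degrees

  int N() const { return n * ncopy; }
  bool adjacent(int r, int s) const {
    if (r / n != s / n) return false;
    int i = r % n, j = s % n;
    if (chain[i] != chain[j]) return false;
    return (i - j == 1) || (j - i == 1);
  }
};

struct Breakdown {
  double conn = 0, ev = 0, xl = 0, box = 0, sub = 0, txl = 0, lat_ev = 0;
  double total() const { return conn + ev + xl + box + sub + txl + lat_ev; }
};

static inline double sdist(const double *a, const double *b, double ra, double rb) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz) - ra - rb;
}

static double box_dist(const double *x, const double *lo, const double *hi) {
  double d2 = 0;
  for (int k = 0; k < 3; k++) {
    double d = 0;
    if (x[k] < lo[k]) d = lo[k] - x[k];
    else if (x[k] > hi[k]) d = x[k] - hi[k];
    d2 += d * d;
  }
  return std::sqrt(d2);
}

// box energy of row r (copy-1 rows mapped back to the copy-0 frame)
static double box_energy_row(const System &S, const std::vector<double> &X, int r) {
  int i = r % S.n;
  if (!S.has_box[i]) return 0;
  const double *x = &X[3 * r];
  double y[3];
  if (r >= S.n) {
    double d[3] = { x[0] - S.t[0], x[1] - S.t[1], x[2] - S.t[2] };
    for (int k = 0; k < 3; k++)            // transpose = inverse rotation
      y[k] = S.R[0 + k] * d[0] + S.R[3 + k] * d[1] + S.R[6 + k] * d[2];
  } else {
    y[0] = x[0]; y[1] = x[1]; y[2] = x[2];
  }
  double d = box_dist(y, &S.blo[3 * i], &S.bhi[3 * i]);
  return S.k_box * d * d;
}

static double xl_energy_one(const System &S, const std::vector<double> &X, int l) {
  int ia = S.xa[l], ib = S.xb[l];
  double best = R_PosInf;
  for (int ca = 0; ca < S.ncopy; ca++) {
    for (int cb = 0; cb < S.ncopy; cb++) {
      // under the symmetry constraint copy 1 is an isometric image of
      // copy 0, so the (1,1) intra-copy distance duplicates (0,0)
      if (S.sym_on && ca == 1 && cb == 1) continue;
      int ra = ca * S.n + ia, rb = cb * S.n + ib;
      if (ra == rb) continue;
      double s = sdist(&X[3 * ra], &X[3 * rb], S.rad[ia], S.rad[ib]);
      if (s < best) best = s;
    }
  }
  if (!R_FINITE(best)) return 0;  // degenerate: both endpoints in one bead, single copy
  double ex = best - S.xbound[l];
  return ex > 0 ? S.xk[l] * ex * ex : 0;
}

// subcomplex group energy, one copy (per-member nearest-neighbour
// distances assembled from the pairwise member-member minima)
static double group_energy_copy(const System &S, const std::vector<double> &X,
                                const std::vector<int> &grp, int cp) {
  size_t m = grp.size();
  std::vector<double> gmin(m, R_PosInf);
  for (size_t a = 0; a + 1 < m; a++) {
    const std::vector<int> &ba = S.comp_beads[grp[a]];
    for (size_t b = a + 1; b < m; b++) {
      const std::vector<int> &bb = S.comp_beads[grp[b]];
      double mab = R_PosInf;
      for (int i : ba) for (int j : bb) {
        double s = sdist(&X[3 * (cp * S.n + i)], &X[3 * (cp * S.n + j)],
                         S.rad[i], S.rad[j]);
        if (s < mab) mab = s;
      }
      if (mab < gmin[a]) gmin[a] = mab;
      if (mab < gmin[b]) gmin[b] = mab;
    }
  }
  double tot = 0;
  for (size_t a = 0; a < m; a++)
    if (R_FINITE(gmin[a]) && gmin[a] > 0) tot += S.k_sub * gmin[a] * gmin[a];
  return tot;
}

// all copies of a group; with the symmetry constraint active, copy 1 is
// isometric to copy 0, so its group energy is identical
static double group_energy_all(const System &S, const std::vector<double> &X,
                               const std::vector<int> &grp) {
  if (S.ncopy == 2 && S.sym_on) return 2.0 * group_energy_copy(S, X, grp, 0);
  double tot = 0;
  for (int cp = 0; cp < S.ncopy; cp++) tot += group_energy_copy(S, X, grp, cp);
  return tot;
}

static double txl_energy_one(const System &S, const std::vector<double> &X,
                             const std::vector<double> &latW, int q) {
  int c = S.tc[q];
  double best = R_PosInf;
  for (int cp = 0; cp < S.ncopy; cp++) {
    const double *x = &X[3 * (cp * S.n + c)];
    for (int j : S.tcand[q]) {
      double s = sdist(x, &latW[3 * j], S.rad[c], S.lrad[j]);
      if (s < best) best = s;
    }
  }
  double ex = best - S.tbound[q];
  return (R_FINITE(best) && ex > 0) ? S.tk[q] * ex * ex : 0;
}

static double lat_ev_row(const System &S, const std::vector<double> &X,
                         const std::vector<double> &latW, int r) {
  double tot = 0;
  const double *x = &X[3 * r];
  double rr = S.rad[r % S.n];
  for (int j = 0; j < S.m; j++) {
    double s = sdist(x, &latW[3 * j], rr, S.lrad[j]);
    if (s < 0) tot += S.lat_ev_k * s * s;
  }
  return tot;
}

static Breakdown full_energy(const System &S, const std::vector<double> &X,
                             const std::vector<double> &latW) {
  Breakdown E;
  int N = S.N();
  // connectivity
  for (int cp = 0; cp < S.ncopy; cp++) {
    for (int i = 0; i + 1 < S.n; i++) {
      if (S.chain[i] != S.chain[i + 1]) continue;
      int r = cp * S.n + i;
      double s = sdist(&X[3 * r], &X[3 * (r + 1)], S.rad[i], S.rad[i + 1]);
      if (s > 0) E.conn += S.k_conn * s * s;
    }
  }
  // excluded volume
  for (int r = 0; r < N; r++) {
    for (int s2 = r + 1; s2 < N; s2++) {
      if (S.adjacent(r, s2)) continue;
      double s = sdist(&X[3 * r], &X[3 * s2], S.rad[r % S.n], S.rad[s2 % S.n]);
      if (s < 0) E.ev += S.k_ev * s * s;
    }
  }
  for (size_t l = 0; l < S.xa.size(); l++) E.xl += xl_energy_one(S, X, l);
  for (int r = 0; r < N; r++) E.box += box_energy_row(S, X, r);
  for (const auto &g : S.groups) E.sub += group_energy_all(S, X, g);
  if (S.has_lat) {
    for (size_t q = 0; q < S.tc.size(); q++) E.txl += txl_energy_one(S, X, latW, q);
    for (int r = 0; r < N; r++) E.lat_ev += lat_ev_row(S, X, latW, r);
  }
  return E;
}

// energy of all terms touching the moved rows (or the lattice).  Called
// before and after a proposal with the same scope, so the difference is
// the exact energy change.
static double local_energy(const System &S, const std::vector<double> &X,
                           const std::vector<double> &latW,
                           const std::vector<int> &M, bool lat_moved,
                           std::vector<char> &in_m, std::vector<char> &xl_seen,
                           std::vector<char> &txl_seen, std::vector<char> &grp_seen) {
  double E = 0;
  int N = S.N();
  if (lat_moved) {
    for (size_t q = 0; q < S.tc.size(); q++) E += txl_energy_one(S, X, latW, q);
    for (int r = 0; r < N; r++) E += lat_ev_row(S, X, latW, r);
    return E;
  }
  for (int r : M) in_m[r] = 1;
  for (int r : M) {
    int i = r % S.n, cp = r / S.n;
    // connectivity edges at r
    for (int dj = -1; dj <= 1; dj += 2) {
      int j = i + dj;
      if (j < 0 || j >= S.n || S.chain[j] != S.chain[i]) continue;
      int rj = cp * S.n + j;
      if (in_m[rj] && rj < r) continue;
      double s = sdist(&X[3 * r], &X[3 * rj], S.rad[i], S.rad[j]);
      if (s > 0) E += S.k_conn * s * s;
    }
    // excluded volume against everything
    for (int s2 = 0; s2 < N; s2++) {
      if (s2 == r) continue;
      if (in_m[s2] && s2 < r) continue;
      if (S.adjacent(r, s2)) continue;
      double s = sdist(&X[3 * r], &X[3 * s2], S.rad[i], S.rad[s2 % S.n]);
      if (s < 0) E += S.k_ev * s * s;
    }
    E += box_energy_row(S, X, r);
    for (int l : S.xl_of_bead[i]) {
      if (xl_seen[l]) continue;
      xl_seen[l] = 1;
      E += xl_energy_one(S, X, l);
    }
    for (size_t gi = 0; gi < S.groups_of_comp[S.comp[i]].size(); gi++) {
      int g = S.groups_of_comp[S.comp[i]][gi];
      if (grp_seen[g]) continue;
      grp_seen[g] = 1;
      E += group_energy_all(S, X, S.groups[g]);
    }
    if (S.has_lat) {
      for (int q : S.txl_of_bead[i]) {
        if (txl_seen[q]) continue;
        txl_seen[q] = 1;
        E += txl_energy_one(S, X, latW, q);
      }
      E += lat_ev_row(S, X, latW, r);
    }
  }
  // reset scratch
  for (int r : M) in_m[r] = 0;
  for (int r : M) {
    int i = r % S.n;
    for (int l : S.xl_of_bead[i]) xl_seen[l] = 0;
    for (int g : S.groups_of_comp[S.comp[i]]) grp_seen[g] = 0;
    if (S.has_lat) for (int q : S.txl_of_bead[i]) txl_seen[q] = 0;
  }
  return E;
}

// ----------------------------------------------------------- builders ----
static void read_mat3(const NumericMatrix &Rm, double *out) {
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) out[3 * i + j] = Rm(i, j);
}

static System build_system(const List &sys) {
  System S;
  S.n = as<int>(sys["n"]);
  S.ncopy = as<int>(sys["ncopy"]);
  S.sym_on = as<bool>(sys["sym_on"]);
  S.rad = as<std::vector<double>>(sys["rad"]);
  S.chain = as<std::vector<int>>(sys["chain"]);
  S.comp = as<std::vector<int>>(sys["comp"]);
  read_mat3(as<NumericMatrix>(sys["symR"]), S.R);
  NumericVector st = sys["symT"];
  for (int k = 0; k < 3; k++) S.t[k] = st[k];
  LogicalVector hb = sys["has_box"];
  S.has_box.assign(hb.begin(), hb.end());
  NumericMatrix lo = sys["box_lo"], hi = sys["box_hi"];
  S.blo.resize(3 * S.n); S.bhi.resize(3 * S.n);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) { S.blo[3 * i + k] = lo(i, k); S.bhi[3 * i + k] = hi(i, k); }
  S.k_conn = as<double>(sys["k_conn"]);
  S.k_ev = as<double>(sys["k_ev"]);
  S.k_box = as<double>(sys["k_box"]);
  S.k_sub = as<double>(sys["k_sub"]);
  S.xa = as<std::vector<int>>(sys["xa"]);
  S.xb = as<std::vector<int>>(sys["xb"]);
  S.xbound = as<std::vector<double>>(sys["xbound"]);
  S.xk = as<std::vector<double>>(sys["xk"]);
  S.xl_of_bead.assign(S.n, {});
  for (size_t l = 0; l < S.xa.size(); l++) {
    S.xl_of_bead[S.xa[l]].push_back((int)l);
    if (S.xb[l] != S.xa[l]) S.xl_of_bead[S.xb[l]].push_back((int)l);
  }
  List gl = sys["groups"];
  for (int g = 0; g < gl.size(); g++)
    S.groups.push_back(as<std::vector<int>>(gl[g]));
  List cb = sys["comp_beads"];
  for (int c = 0; c < cb.size(); c++)
    S.comp_beads.push_back(as<std::vector<int>>(cb[c]));
  S.groups_of_comp.assign(S.comp_beads.size(), {});
  for (size_t g = 0; g < S.groups.size(); g++)
    for (int c : S.groups[g]) S.groups_of_comp[c].push_back((int)g);
  if (sys.containsElementNamed("lattice") && !Rf_isNull(sys["lattice"])) {
    List lat = sys["lattice"];
    S.has_lat = true;
    NumericMatrix L0 = lat["L0"];
    S.m = L0.nrow();
    S.L0.resize(3 * S.m);
    for (int j = 0; j < S.m; j++)
      for (int k = 0; k < 3; k++) S.L0[3 * j + k] = L0(j, k);
    S.lrad = as<std::vector<double>>(lat["lrad"]);
    S.lsub = as<std::vector<int>>(lat["lsub"]);
    S.nsub = as<int>(lat["nsub"]);
    S.lat_ev_k = as<double>(lat["ev_k"]);
    S.tc = as<std::vector<int>>(lat["tc"]);
    List tcand = lat["tcand"];
    for (int q = 0; q < tcand.size(); q++)
      S.tcand.push_back(as<std::vector<int>>(tcand[q]));
    S.tbound = as<std::vector<double>>(lat["tbound"]);
    S.tk = as<std::vector<double>>(lat["tk"]);
    S.txl_of_bead.assign(S.n, {});
    for (size_t q = 0; q < S.tc.size(); q++)
      S.txl_of_bead[S.tc[q]].push_back((int)q);
    S.lat_max_trans = as<double>(lat["max_trans"]);
    S.lat_max_rot = as<double>(lat["max_rot"]);
  }
  return S;
}

static void lat_world(const System &S, const double *latR, const double *latT,
                      std::vector<double> &latW) {
  latW.resize(3 * S.m);
  for (int j = 0; j < S.m; j++) {
    const double *x = &S.L0[3 * j];
    for (int k = 0; k < 3; k++)
      latW[3 * j + k] = latR[3 * k] * x[0] + latR[3 * k + 1] * x[1] +
                        latR[3 * k + 2] * x[2] + latT[k];
  }
}

// ------------------------------------------------------------ exports ----

//' @noRd
// [[Rcpp::export(name = ".cg_energy_cpp")]]
NumericVector cg_energy_cpp(List sys, NumericMatrix X,
                            Nullable<NumericMatrix> latR = R_NilValue,
                            Nullable<NumericVector> latT = R_NilValue) {
  System S = build_system(sys);
  std::vector<double> Xv(3 * X.nrow());
  for (int r = 0; r < X.nrow(); r++)
    for (int k = 0; k < 3; k++) Xv[3 * r + k] = X(r, k);
  std::vector<double> latW;
  if (S.has_lat) {
    double Rm[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1}, Tv[3] = {0, 0, 0};
    if (latR.isNotNull()) read_mat3(NumericMatrix(latR), Rm);
    if (latT.isNotNull()) {
      NumericVector tv(latT);
      for (int k = 0; k < 3; k++) Tv[k] = tv[k];
    }
    lat_world(S, Rm, Tv, latW);
  }
  Breakdown E = full_energy(S, Xv, latW);
  return NumericVector::create(
    _["connectivity"] = E.conn, _["excluded_volume"] = E.ev,
    _["crosslink"] = E.xl, _["box"] = E.box, _["subcomplex"] = E.sub,
    _["tubulin_xl"] = E.txl, _["lattice_ev"] = E.lat_ev,
    _["total"] = E.total());
}

struct Replica {
  std::vector<double> X;
  double E = 0;
  double latR[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double latT[3] = {0, 0, 0};
  std::vector<double> latW;
  Xoshiro rng;
  long long n_prop = 0, n_acc = 0;
  // WTE bias (attached to the temperature slot)
  std::vector<double> wE, wH;
};

static double wte_value(const Replica &rep, double sigma, double e) {
  double v = 0;
  for (size_t k = 0; k < rep.wE.size(); k++) {
    double d = (e - rep.wE[k]) / sigma;
    v += rep.wH[k] * std::exp(-0.5 * d * d);
  }
  return v;
}

static void apply_sym_row(const System &S, std::vector<double> &X, int i) {
  const double *x = &X[3 * i];
  double *y = &X[3 * (S.n + i)];
  for (int k = 0; k < 3; k++)
    y[k] = S.R[3 * k] * x[0] + S.R[3 * k + 1] * x[1] + S.R[3 * k + 2] * x[2] + S.t[k];
}

static void rot_axis_angle(const double *u, double ang, double *Rm) {
  double c = std::cos(ang), s = std::sin(ang), C = 1 - c;
  Rm[0] = c + u[0] * u[0] * C;       Rm[1] = u[0] * u[1] * C - u[2] * s; Rm[2] = u[0] * u[2] * C + u[1] * s;
  Rm[3] = u[1] * u[0] * C + u[2] * s; Rm[4] = c + u[1] * u[1] * C;       Rm[5] = u[1] * u[2] * C - u[0] * s;
  Rm[6] = u[2] * u[0] * C - u[1] * s; Rm[7] = u[2] * u[1] * C + u[0] * s; Rm[8] = c + u[2] * u[2] * C;
}

// one MC step on one replica; returns proposal energy change (dE) via out
static bool mc_one_step(const System &S, Replica &rep, double temp,
                        double max_move, double lat_move_prob, bool lat_mobile,
                        bool wte_on, double wte_sigma,
                        std::vector<char> &in_m, std::vector<char> &xl_seen,
                        std::vector<char> &txl_seen, std::vector<char> &grp_seen,
                        double *dE_out) {
  rep.n_prop++;
  bool lat_move = S.has_lat && lat_mobile && rep.rng.unif() < lat_move_prob;
  double dE = 0;
  std::vector<int> M;
  double oldR[9], oldT[3];
  std::vector<double> oldW;
  double old_xyz[6];
  int moved_rows[2] = {-1, -1};
  if (lat_move) {
    double before = local_energy(S, rep.X, rep.latW, M, true, in_m, xl_seen, txl_seen, grp_seen);
    std::copy(rep.latR, rep.latR + 9, oldR);
    std::copy(rep.latT, rep.latT + 3, oldT);
    oldW = rep.latW;
    if (rep.rng.unif() < 0.5) {
      double v[3];
      rep.rng.ball(v);
      for (int k = 0; k < 3; k++) rep.latT[k] += v[k] * S.lat_max_trans;
      for (int j = 0; j < S.m; j++)
        for (int k = 0; k < 3; k++) rep.latW[3 * j + k] += (rep.latT[k] - oldT[k]);
    } else {
      double u[3];
      rep.rng.ball(u);
      double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      for (int k = 0; k < 3; k++) u[k] /= nu;
      double ang = (2.0 * rep.rng.unif() - 1.0) * S.lat_max_rot * M_PI / 180.0;
      double Q[9];
      rot_axis_angle(u, ang, Q);
      // rotate about the current lattice centroid
      double cen[3] = {0, 0, 0};
      for (int j = 0; j < S.m; j++)
        for (int k = 0; k < 3; k++) cen[k] += rep.latW[3 * j + k];
      for (int k = 0; k < 3; k++) cen[k] /= S.m;
      double newR[9], d[3];
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++) {
          newR[3 * i + j] = 0;
          for (int k = 0; k < 3; k++) newR[3 * i + j] += Q[3 * i + k] * rep.latR[3 * k + j];
        }
      for (int k = 0; k < 3; k++) d[k] = rep.latT[k] - cen[k];
      for (int k = 0; k < 3; k++)
        rep.latT[k] = cen[k] + Q[3 * k] * d[0] + Q[3 * k + 1] * d[1] + Q[3 * k + 2] * d[2];
      std::copy(newR, newR + 9, rep.latR);
      lat_world(S, rep.latR, rep.latT, rep.latW);
    }
    double after = local_energy(S, rep.X, rep.latW, M, true, in_m, xl_seen, txl_seen, grp_seen);
    dE = after - before;
  } else {
    int n_mov = S.sym_on ? S.n : S.N();
    int r = rep.rng.randint(n_mov);
    M.push_back(r);
    moved_rows[0] = r;
    if (S.sym_on && S.ncopy == 2) {
      M.push_back(S.n + r);
      moved_rows[1] = S.n + r;
    }
    double before = local_energy(S, rep.X, rep.latW, M, false, in_m, xl_seen, txl_seen, grp_seen);
    for (size_t q = 0; q < M.size(); q++)
      for (int k = 0; k < 3; k++) old_xyz[3 * q + k] = rep.X[3 * M[q] + k];
    double v[3];
    rep.rng.ball(v);
    for (int k = 0; k < 3; k++) rep.X[3 * r + k] += v[k] * max_move;
    if (S.sym_on && S.ncopy == 2) apply_sym_row(S, rep.X, r);
    double after = local_energy(S, rep.X, rep.latW, M, false, in_m, xl_seen, txl_seen, grp_seen);
    dE = after - before;
  }
  double dEff = dE;
  if (wte_on) dEff = dE + wte_value(rep, wte_sigma, rep.E + dE) - wte_value(rep, wte_sigma, rep.E);
  bool accept = dEff <= 0 || rep.rng.unif() < std::exp(-dEff / temp);
  if (accept) {
    rep.E += dE;
    rep.n_acc++;
  } else {
    if (lat_move) {
      std::copy(oldR, oldR + 9, rep.latR);
      std::copy(oldT, oldT + 3, rep.latT);
      rep.latW = oldW;
    } else {
      for (size_t q = 0; q < M.size(); q++)
        for (int k = 0; k < 3; k++) rep.X[3 * M[q] + k] = old_xyz[3 * q + k];
    }
  }
  if (dE_out) *dE_out = dE;
  (void)moved_rows;
  return accept;
}

//' @noRd
// [[Rcpp::export(name = ".pt_run_cpp")]]
List pt_run_cpp(List sys, NumericMatrix X0, List cfg) {
  System S = build_system(sys);
  NumericVector temps = cfg["temps"];
  int nrep = temps.size();
  long long n_steps = (long long)as<double>(cfg["n_steps"]);
  long long exch = (long long)as<double>(cfg["exchange_interval"]);
  if (exch < 1) exch = 1;
  double max_move = as<double>(cfg["max_move"]);
  uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  int top_n = as<int>(cfg["top_n"]);
  bool trace = as<bool>(cfg["trace"]);
  bool diag = as<bool>(cfg["diag"]);
  bool lat_mobile = cfg.containsElementNamed("lat_mobile") ? as<bool>(cfg["lat_mobile"]) : false;
  bool wte_on = as<bool>(cfg["wte_enabled"]);
  double wte_gamma = as<double>(cfg["wte_gamma"]);
  double wte_sigma = as<double>(cfg["wte_sigma"]);
  double wte_height = as<double>(cfg["wte_height"]);
  if (wte_on && wte_gamma <= 1) stop("well-tempered gamma must be > 1");

  int N = S.N();
  if (X0.nrow() != N) stop("coordinate matrix has wrong number of rows");
  double lat_move_prob = 0;
  if (S.has_lat && lat_mobile) {
    lat_move_prob = 1.0 / ((S.sym_on ? S.n : N) + 1.0);
    if (cfg.containsElementNamed("lat_move_prob") && !Rf_isNull(cfg["lat_move_prob"]))
      lat_move_prob = as<double>(cfg["lat_move_prob"]);
  }

  std::vector<Replica> reps(nrep);
  double R0[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1}, T0[3] = {0, 0, 0};
  if (cfg.containsElementNamed("latR") && !Rf_isNull(cfg["latR"])) {
    read_mat3(as<NumericMatrix>(cfg["latR"]), R0);
    NumericVector t0 = cfg["latT"];
    for (int k = 0; k < 3; k++) T0[k] = t0[k];
  }
  std::vector<char> in_m(N, 0), xl_seen(S.xa.size(), 0),
      txl_seen(S.tc.size(), 0), grp_seen(S.groups.size(), 0);
  for (int r = 0; r < nrep; r++) {
    reps[r].X.resize(3 * N);
    for (int i = 0; i < N; i++)
      for (int k = 0; k < 3; k++) reps[r].X[3 * i + k] = X0(i, k);
    std::copy(R0, R0 + 9, reps[r].latR);
    std::copy(T0, T0 + 3, reps[r].latT);
    if (S.has_lat) lat_world(S, reps[r].latR, reps[r].latT, reps[r].latW);
    reps[r].rng.seed(seed * 0x9E3779B97f4A7C15ULL + 1000003ULL * (r + 1));
    reps[r].E = full_energy(S, reps[r].X, reps[r].latW).total();
  }
  Xoshiro master;
  master.seed(seed * 0xD1B54A32D192ED03ULL + 7919ULL);

  // snapshot store (lowest-temperature slot only)
  std::vector<std::vector<double>> snapX;
  std::vector<double> snapE, snapStep;
  std::vector<std::vector<double>> snapPose; // 12 numbers R|t
  auto record = [&](long long step) {
    Replica &r0 = reps[0];
    double Efull = full_energy(S, r0.X, r0.latW).total();
    r0.E = Efull;
    snapX.push_back(r0.X);
    snapE.push_back(Efull);
    snapStep.push_back((double)step);
    if (S.has_lat) {
      std::vector<double> p(12);
      std::copy(r0.latR, r0.latR + 9, p.begin());
      std::copy(r0.latT, r0.latT + 3, p.begin() + 9);
      snapPose.push_back(p);
    }
    if ((int)snapX.size() > std::max(4 * top_n, 4000)) {
      std::vector<int> idx(snapX.size());
      for (size_t i = 0; i < idx.size(); i++) idx[i] = (int)i;
      std::stable_sort(idx.begin(), idx.end(),
                       [&](int a, int b) { return snapE[a] < snapE[b]; });
      idx.resize(top_n);
      std::vector<std::vector<double>> nx;
      std::vector<double> ne, ns;
      std::vector<std::vector<double>> np;
      for (int i : idx) {
        nx.push_back(snapX[i]); ne.push_back(snapE[i]); ns.push_back(snapStep[i]);
        if (S.has_lat) np.push_back(snapPose[i]);
      }
      snapX.swap(nx); snapE.swap(ne); snapStep.swap(ns); snapPose.swap(np);
    }
  };

  long long n_sweeps = (n_steps + exch - 1) / exch;
  std::vector<double> trE, trX, trY, trZ;  // sweeps x nrep, column-major by sweep
  std::vector<double> diag_dE;
  std::vector<int> diag_acc;
  long long exch_prop = 0, exch_acc = 0;

  record(0);
  long long done = 0;
  for (long long sweep = 0; sweep < n_sweeps; sweep++) {
    long long todo = std::min(exch, n_steps - done);
    for (int r = 0; r < nrep; r++) {
      for (long long s = 0; s < todo; s++) {
        double dE;
        bool acc = mc_one_step(S, reps[r], temps[r], max_move, lat_move_prob,
                               lat_mobile, wte_on, wte_sigma, in_m, xl_seen,
                               txl_seen, grp_seen, &dE);
        if (diag && r == 0) {
          diag_dE.push_back(dE);
          diag_acc.push_back(acc ? 1 : 0);
        }
      }
    }
    done += todo;
    // refresh cached energies (guards against incremental drift)
    for (int r = 0; r < nrep; r++)
      reps[r].E = full_energy(S, reps[r].X, reps[r].latW).total();
    // WTE deposit
    if (wte_on) {
      for (int r = 0; r < nrep; r++) {
        double V = wte_value(reps[r], wte_sigma, reps[r].E);
        double h = wte_height * std::exp(-V / ((wte_gamma - 1.0) * temps[r]));
        reps[r].wE.push_back(reps[r].E);
        reps[r].wH.push_back(h);
      }
    }
    // replica exchange, alternating even/odd pairing
    if (nrep > 1) {
      int start = (int)(sweep % 2);
      for (int k = start; k + 1 < nrep; k += 2) {
        exch_prop++;
        double bi = 1.0 / temps[k], bj = 1.0 / temps[k + 1];
        double Ui = reps[k].E, Uj = reps[k + 1].E;
        double del;
        if (wte_on) {
          del = bi * (Ui + wte_value(reps[k], wte_sigma, Ui) - Uj - wte_value(reps[k], wte_sigma, Uj)) +
                bj * (Uj + wte_value(reps[k + 1], wte_sigma, Uj) - Ui - wte_value(reps[k + 1], wte_sigma, Ui));
        } else {
          del = (bi - bj) * (Ui - Uj);
        }
        if (del >= 0 || master.unif() < std::exp(del)) {
          exch_acc++;
          std::swap(reps[k].X, reps[k + 1].X);
          std::swap(reps[k].E, reps[k + 1].E);
          for (int q = 0; q < 9; q++) std::swap(reps[k].latR[q], reps[k + 1].latR[q]);
          for (int q = 0; q < 3; q++) std::swap(reps[k].latT[q], reps[k + 1].latT[q]);
          std::swap(reps[k].latW, reps[k + 1].latW);
        }
      }
    }
    if (trace) {
      for (int r = 0; r < nrep; r++) {
        trE.push_back(reps[r].E);
        trX.push_back(reps[r].X[0]);
        trY.push_back(reps[r].X[1]);
        trZ.push_back(reps[r].X[2]);
      }
    }
    record(done);
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // final top-N selection
  std::vector<int> idx(snapX.size());
  for (size_t i = 0; i < idx.size(); i++) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return snapE[a] < snapE[b]; });
  if ((int)idx.size() > top_n) idx.resize(top_n);
  List snaps(idx.size());
  NumericVector scores(idx.size()), steps(idx.size());
  List poses(idx.size());
  for (size_t i = 0; i < idx.size(); i++) {
    NumericMatrix Xi(N, 3);
    for (int r = 0; r < N; r++)
      for (int k = 0; k < 3; k++) Xi(r, k) = snapX[idx[i]][3 * r + k];
    snaps[i] = Xi;
    scores[i] = snapE[idx[i]];
    steps[i] = snapStep[idx[i]];
    if (S.has_lat) {
      NumericMatrix Rm(3, 3);
      NumericVector tv(3);
      for (int a = 0; a < 3; a++)
        for (int b = 0; b < 3; b++) Rm(a, b) = snapPose[idx[i]][3 * a + b];
      for (int k = 0; k < 3; k++) tv[k] = snapPose[idx[i]][9 + k];
      poses[i] = List::create(_["R"] = Rm, _["t"] = tv);
    }
  }
  List finals(nrep);
  NumericVector finalE(nrep), accrate(nrep);
  for (int r = 0; r < nrep; r++) {
    NumericMatrix Xf(N, 3);
    for (int i = 0; i < N; i++)
      for (int k = 0; k < 3; k++) Xf(i, k) = reps[r].X[3 * i + k];
    NumericMatrix Rm(3, 3);
    NumericVector tv(3);
    for (int a = 0; a < 3; a++)
      for (int b = 0; b < 3; b++) Rm(a, b) = reps[r].latR[3 * a + b];
    for (int k = 0; k < 3; k++) tv[k] = reps[r].latT[k];
    finals[r] = List::create(_["X"] = Xf, _["energy"] = reps[r].E,
                             _["latR"] = Rm, _["latT"] = tv);
    finalE[r] = reps[r].E;
    accrate[r] = reps[r].n_prop > 0 ? (double)reps[r].n_acc / reps[r].n_prop : NA_REAL;
  }
  List out = List::create(
    _["snapshots"] = snaps, _["scores"] = scores, _["steps"] = steps,
    _["poses"] = poses, _["finals"] = finals, _["final_energies"] = finalE,
    _["acceptance"] = accrate,
    _["exchange_rate"] = exch_prop > 0 ? (double)exch_acc / exch_prop : NA_REAL);
  if (trace) {
    long long nsw = trE.size() / nrep;
    NumericMatrix mE(nsw, nrep), mX(nsw, nrep), mY(nsw, nrep), mZ(nsw, nrep);
    for (long long s = 0; s < nsw; s++)
      for (int r = 0; r < nrep; r++) {
        mE(s, r) = trE[s * nrep + r];
        mX(s, r) = trX[s * nrep + r];
        mY(s, r) = trY[s * nrep + r];
        mZ(s, r) = trZ[s * nrep + r];
      }
    out["trace_energy"] = mE;
    out["trace_x"] = mX;
    out["trace_y"] = mY;
    out["trace_z"] = mZ;
  }
  if (diag) {
    out["diag_dE"] = NumericVector(diag_dE.begin(), diag_dE.end());
    out["diag_accepted"] = IntegerVector(diag_acc.begin(), diag_acc.end());
  }
  return out;
}
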