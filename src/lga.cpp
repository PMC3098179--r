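// Hot path of the docking engine: portable RNG, pose construction from a
// genome (translation + quaternion + relative torsions), trilinear grid
// interpolation, intra/intermolecular scoring, Solis-Wets local search and
// the Lamarckian GA run. Everything here is bit-deterministic given a seed:
// no system RNG, no time, no thread-dependent state.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64. One independent stream per
// LGA run; identical seeds give identical draw sequences on any platform.
// ---------------------------------------------------------------------------

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  uint64_t next() {
    const uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normal, Box-Muller (uncached: draw count per call is fixed,
  // which keeps stream positions easy to reason about)
  double norm() {
    double u1 = unif(), u2 = unif();
    if (u1 <= 0.0) u1 = 0x1.0p-53;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }

  // standard Cauchy
  double cauchy() { return std::tan(M_PI * (unif() - 0.5)); }
};

// ---------------------------------------------------------------------------
// Quaternions (w, x, y, z)
// ---------------------------------------------------------------------------

struct Quat {
  double w, x, y, z;
};

static inline Quat q_mul(const Quat& a, const Quat& b) {
  Quat r;
  r.w = a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z;
  r.x = a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y;
  r.y = a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x;
  r.z = a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w;
  return r;
}

static inline void q_normalize(Quat& q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  if (n <= 0.0) { q.w = 1.0; q.x = q.y = q.z = 0.0; return; }
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

static inline Quat q_from_axis_angle(double ax, double ay, double az,
                                     double angle) {
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  Quat q;
  if (n <= 0.0) { q.w = 1.0; q.x = q.y = q.z = 0.0; return q; }
  double s = std::sin(angle / 2.0) / n;
  q.w = std::cos(angle / 2.0);
  q.x = ax * s; q.y = ay * s; q.z = az * s;
  return q;
}

// rotation-vector (axis * angle, radians) -> quaternion
static inline Quat q_from_rotvec(double rx, double ry, double rz) {
  double angle = std::sqrt(rx * rx + ry * ry + rz * rz);
  if (angle <= 0.0) { Quat q; q.w = 1.0; q.x = q.y = q.z = 0.0; return q; }
  return q_from_axis_angle(rx, ry, rz, angle);
}

// 3x3 rotation matrix from a unit quaternion
static inline void q_to_mat(const Quat& q, double R[9]) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// Shoemake uniform random unit quaternion
static inline Quat q_random(Xoshiro& rng) {
  double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
  double s1 = std::sqrt(1.0 - u1), s2 = std::sqrt(u1);
  Quat q;
  q.w = s2 * std::cos(2.0 * M_PI * u3);
  q.x = s1 * std::sin(2.0 * M_PI * u2);
  q.y = s1 * std::cos(2.0 * M_PI * u2);
  q.z = s2 * std::sin(2.0 * M_PI * u3);
  q_normalize(q);
  return q;
}

// ---------------------------------------------------------------------------
// Grid maps and trilinear interpolation
// ---------------------------------------------------------------------------

struct Map {
  const double* v;  // (n)^3 values, x-fastest
  int n;            // points per axis (npts + 1)
  double sp;        // spacing, Angstrom
  double ox, oy, oz;  // origin (lower corner)
};

static const double OUT_OF_GRID_PENALTY = 1.0e5;

static inline bool in_box(const Map& m, double x, double y, double z) {
  double hi = (m.n - 1) * m.sp;
  return x >= m.ox && x <= m.ox + hi && y >= m.oy && y <= m.oy + hi &&
         z >= m.oz && z <= m.oz + hi;
}

// trilinear blend of the 8 surrounding lattice values; caller guarantees
// the point is inside the box (upper faces handled by clamping the cell)
static double trilinear(const Map& m, double x, double y, double z) {
  double ux = (x - m.ox) / m.sp, uy = (y - m.oy) / m.sp, uz = (z - m.oz) / m.sp;
  int ix = (int)std::floor(ux), iy = (int)std::floor(uy), iz = (int)std::floor(uz);
  if (ix > m.n - 2) ix = m.n - 2;
  if (iy > m.n - 2) iy = m.n - 2;
  if (iz > m.n - 2) iz = m.n - 2;
  if (ix < 0) ix = 0;
  if (iy < 0) iy = 0;
  if (iz < 0) iz = 0;
  double fx = ux - ix, fy = uy - iy, fz = uz - iz;
  int n = m.n;
  const double* v = m.v;
#define VAL(a, b, c) v[(ix + (a)) + n * ((iy + (b)) + n * (iz + (c)))]
  double c00 = VAL(0, 0, 0) * (1 - fx) + VAL(1, 0, 0) * fx;
  double c10 = VAL(0, 1, 0) * (1 - fx) + VAL(1, 1, 0) * fx;
  double c01 = VAL(0, 0, 1) * (1 - fx) + VAL(1, 0, 1) * fx;
  double c11 = VAL(0, 1, 1) * (1 - fx) + VAL(1, 1, 1) * fx;
#undef VAL
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static Map map_from_list(const List& ml) {
  Map m;
  NumericVector v = ml["values"];
  NumericVector org = ml["origin"];
  m.v = REAL(v);
  m.n = as<int>(ml["n"]);
  m.sp = as<double>(ml["spacing"]);
  m.ox = org[0]; m.oy = org[1]; m.oz = org[2];
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_interpolate(List map, NumericMatrix points) {
  Map m = map_from_list(map);
  int np = points.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    out[i] = in_box(m, x, y, z) ? trilinear(m, x, y, z) : OUT_OF_GRID_PENALTY;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Ligand model shared by scoring and search
// ---------------------------------------------------------------------------

struct Edge {
  int i, j;                 // 0-based bond atom indices (proximal, distal)
  std::vector<int> moved;   // 0-based atoms rotated by this torsion
};

struct Ligand {
  int natoms;
  std::vector<double> x0, y0, z0;  // input coordinates
  std::vector<double> q;           // partial charges
  std::vector<int> type;           // 0-based index into affinity map vector
  std::vector<int> root;           // 0-based root-group atom indices
  std::vector<Edge> edges;         // pre-order (root outward)
  // eligible nonbonded pairs for the internal term
  std::vector<int> pi, pj;
  std::vector<double> peps, psig, pqq;
};

struct Genome {
  double t[3];
  Quat q;
  std::vector<double> tor;  // degrees, relative to the input conformation
};

static const double COULOMB_K = 332.0636;  // kcal*A/(mol*e^2)
static const double R_MIN = 0.01;          // floor on pair distances, A

static inline double wrap_deg(double a) {
  a -= 360.0 * std::floor(a / 360.0);  // [0, 360)
  if (a > 180.0) a -= 360.0;           // (-180, 180]
  return a;
}

// Apply a genome to the input coordinates: torsions root-outward (right-hand
// rule looking from proximal to distal bond atom), then rigid rotation about
// the root-group centroid, then translation of that centroid to t.
static void apply_genome(const Ligand& L, const Genome& g,
                         std::vector<double>& X, std::vector<double>& Y,
                         std::vector<double>& Z) {
  int n = L.natoms;
  X.assign(L.x0.begin(), L.x0.end());
  Y.assign(L.y0.begin(), L.y0.end());
  Z.assign(L.z0.begin(), L.z0.end());
  for (size_t k = 0; k < L.edges.size(); ++k) {
    const Edge& e = L.edges[k];
    double ax = X[e.j] - X[e.i], ay = Y[e.j] - Y[e.i], az = Z[e.j] - Z[e.i];
    double nrm = std::sqrt(ax * ax + ay * ay + az * az);
    if (nrm <= 0.0) continue;
    ax /= nrm; ay /= nrm; az /= nrm;
    double ang = g.tor[k] * M_PI / 180.0;
    double c = std::cos(ang), s = std::sin(ang);
    double px = X[e.i], py = Y[e.i], pz = Z[e.i];
    for (size_t m = 0; m < e.moved.size(); ++m) {
      int a = e.moved[m];
      double vx = X[a] - px, vy = Y[a] - py, vz = Z[a] - pz;
      double dot = ax * vx + ay * vy + az * vz;
      // Rodrigues
      double rx = vx * c + (ay * vz - az * vy) * s + ax * dot * (1 - c);
      double ry = vy * c + (az * vx - ax * vz) * s + ay * dot * (1 - c);
      double rz = vz * c + (ax * vy - ay * vx) * s + az * dot * (1 - c);
      X[a] = px + rx; Y[a] = py + ry; Z[a] = pz + rz;
    }
  }
  // root-group centroid (torsions never move root atoms)
  double cx = 0, cy = 0, cz = 0;
  for (size_t m = 0; m < L.root.size(); ++m) {
    cx += X[L.root[m]]; cy += Y[L.root[m]]; cz += Z[L.root[m]];
  }
  cx /= L.root.size(); cy /= L.root.size(); cz /= L.root.size();
  double R[9];
  Quat qn = g.q;
  q_normalize(qn);
  q_to_mat(qn, R);
  for (int a = 0; a < n; ++a) {
    double vx = X[a] - cx, vy = Y[a] - cy, vz = Z[a] - cz;
    X[a] = R[0] * vx + R[1] * vy + R[2] * vz + g.t[0];
    Y[a] = R[3] * vx + R[4] * vy + R[5] * vz + g.t[1];
    Z[a] = R[6] * vx + R[7] * vy + R[8] * vz + g.t[2];
  }
}

// grid part: affinity + q*electrostatic + |q|*desolvation per atom;
// an atom outside the box contributes the penalty once and skips its maps
static double inter_energy(const Ligand& L, const std::vector<Map>& aff,
                           const Map& em, const Map& dm,
                           const std::vector<double>& X,
                           const std::vector<double>& Y,
                           const std::vector<double>& Z) {
  double e = 0.0;
  for (int a = 0; a < L.natoms; ++a) {
    const Map& m = aff[L.type[a]];
    if (!in_box(m, X[a], Y[a], Z[a])) {
      e += OUT_OF_GRID_PENALTY;
      continue;
    }
    e += trilinear(m, X[a], Y[a], Z[a]);
    e += L.q[a] * trilinear(em, X[a], Y[a], Z[a]);
    e += std::fabs(L.q[a]) * trilinear(dm, X[a], Y[a], Z[a]);
  }
  return e;
}

// 12-6 Lennard-Jones + Coulomb with distance-dependent dielectric eps_r = 4r
static double internal_energy_cpp(const Ligand& L, const std::vector<double>& X,
                                  const std::vector<double>& Y,
                                  const std::vector<double>& Z) {
  double e = 0.0;
  for (size_t k = 0; k < L.pi.size(); ++k) {
    int i = L.pi[k], j = L.pj[k];
    double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < R_MIN) r = R_MIN;
    double sr = L.psig[k] / r;
    double sr6 = sr * sr * sr;
    sr6 = sr6 * sr6;
    e += 4.0 * L.peps[k] * (sr6 * sr6 - sr6);
    e += COULOMB_K * L.pqq[k] / (4.0 * r * r);  // qq/(eps_r * r), eps_r = 4r
  }
  return e;
}

struct Scorer {
  const Ligand* L;
  std::vector<Map> aff;
  Map em, dm;
  long evals;
  std::vector<double> X, Y, Z;  // scratch

  double score(const Genome& g, double* inter_out = 0, double* intra_out = 0) {
    apply_genome(*L, g, X, Y, Z);
    double ei = inter_energy(*L, aff, em, dm, X, Y, Z);
    double ea = internal_energy_cpp(*L, X, Y, Z);
    ++evals;
    if (inter_out) *inter_out = ei;
    if (intra_out) *intra_out = ea;
    return ei + ea;
  }
};

static Ligand ligand_from_args(NumericMatrix coords, NumericVector charges,
                               IntegerVector type_idx, IntegerVector root_idx,
                               List edges, List pairs) {
  Ligand L;
  L.natoms = coords.nrow();
  L.x0.resize(L.natoms); L.y0.resize(L.natoms); L.z0.resize(L.natoms);
  L.q.resize(L.natoms); L.type.resize(L.natoms);
  for (int a = 0; a < L.natoms; ++a) {
    L.x0[a] = coords(a, 0); L.y0[a] = coords(a, 1); L.z0[a] = coords(a, 2);
    L.q[a] = charges[a];
    L.type[a] = type_idx[a] - 1;
  }
  for (int m = 0; m < root_idx.size(); ++m) L.root.push_back(root_idx[m] - 1);
  for (int k = 0; k < edges.size(); ++k) {
    List ek = edges[k];
    Edge e;
    e.i = as<int>(ek["i"]) - 1;
    e.j = as<int>(ek["j"]) - 1;
    IntegerVector mv = ek["moved"];
    for (int m = 0; m < mv.size(); ++m) e.moved.push_back(mv[m] - 1);
    L.edges.push_back(e);
  }
  if (pairs.size() > 0) {
    IntegerVector pi = pairs["i"], pj = pairs["j"];
    NumericVector pe = pairs["eps"], ps = pairs["sigma"], pq = pairs["qq"];
    for (int k = 0; k < pi.size(); ++k) {
      L.pi.push_back(pi[k] - 1);
      L.pj.push_back(pj[k] - 1);
      L.peps.push_back(pe[k]);
      L.psig.push_back(ps[k]);
      L.pqq.push_back(pq[k]);
    }
  }
  return L;
}

static std::vector<Map> maps_from_list(List aff_maps) {
  std::vector<Map> v;
  for (int k = 0; k < aff_maps.size(); ++k) v.push_back(map_from_list(aff_maps[k]));
  return v;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_state(NumericMatrix coords, IntegerVector root_idx,
                              List edges, NumericVector trans,
                              NumericVector quat, NumericVector torsions) {
  Ligand L;
  L.natoms = coords.nrow();
  L.x0.resize(L.natoms); L.y0.resize(L.natoms); L.z0.resize(L.natoms);
  L.q.assign(L.natoms, 0.0); L.type.assign(L.natoms, 0);
  for (int a = 0; a < L.natoms; ++a) {
    L.x0[a] = coords(a, 0); L.y0[a] = coords(a, 1); L.z0[a] = coords(a, 2);
  }
  for (int m = 0; m < root_idx.size(); ++m) L.root.push_back(root_idx[m] - 1);
  for (int k = 0; k < edges.size(); ++k) {
    List ek = edges[k];
    Edge e;
    e.i = as<int>(ek["i"]) - 1;
    e.j = as<int>(ek["j"]) - 1;
    IntegerVector mv = ek["moved"];
    for (int m = 0; m < mv.size(); ++m) e.moved.push_back(mv[m] - 1);
    L.edges.push_back(e);
  }
  Genome g;
  g.t[0] = trans[0]; g.t[1] = trans[1]; g.t[2] = trans[2];
  g.q.w = quat[0]; g.q.x = quat[1]; g.q.y = quat[2]; g.q.z = quat[3];
  for (int k = 0; k < torsions.size(); ++k) g.tor.push_back(torsions[k]);
  std::vector<double> X, Y, Z;
  apply_genome(L, g, X, Y, Z);
  NumericMatrix out(L.natoms, 3);
  for (int a = 0; a < L.natoms; ++a) {
    out(a, 0) = X[a]; out(a, 1) = Y[a]; out(a, 2) = Z[a];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_score(NumericMatrix coords, NumericVector charges,
               IntegerVector type_idx, IntegerVector root_idx, List edges,
               List pairs, List aff_maps, List emap, List dmap,
               NumericVector trans, NumericVector quat,
               NumericVector torsions) {
  Ligand L = ligand_from_args(coords, charges, type_idx, root_idx, edges, pairs);
  Scorer S;
  S.L = &L;
  S.aff = maps_from_list(aff_maps);
  S.em = map_from_list(emap);
  S.dm = map_from_list(dmap);
  S.evals = 0;
  Genome g;
  g.t[0] = trans[0]; g.t[1] = trans[1]; g.t[2] = trans[2];
  g.q.w = quat[0]; g.q.x = quat[1]; g.q.y = quat[2]; g.q.z = quat[3];
  for (int k = 0; k < torsions.size(); ++k) g.tor.push_back(torsions[k]);
  double inter, intra;
  double tot = S.score(g, &inter, &intra);
  return List::create(_["intermolecular"] = inter, _["internal"] = intra,
                      _["total"] = tot);
}

// [[Rcpp::export]]
NumericMatrix cpp_internal_pairs_energy(NumericMatrix coords, List pairs) {
  // per-pair energies, used by the R-level internal_energy wrapper
  IntegerVector pi = pairs["i"], pj = pairs["j"];
  NumericVector pe = pairs["eps"], ps = pairs["sigma"], pq = pairs["qq"];
  int np = pi.size();
  NumericMatrix out(np, 2);  // columns: LJ, Coulomb
  for (int k = 0; k < np; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double dx = coords(i, 0) - coords(j, 0);
    double dy = coords(i, 1) - coords(j, 1);
    double dz = coords(i, 2) - coords(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < R_MIN) r = R_MIN;
    double sr = ps[k] / r;
    double sr6 = sr * sr * sr;
    sr6 = sr6 * sr6;
    out(k, 0) = 4.0 * pe[k] * (sr6 * sr6 - sr6);
    out(k, 1) = COULOMB_K * pq[k] / (4.0 * r * r);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Solis-Wets local search
// ---------------------------------------------------------------------------

struct SwParams {
  double rho0, rho_min;
  int max_consec;  // successes before expansion / failures before contraction
};

// genome-space increment: translation += d[0:3]; orientation composed with
// rotation vector d[3:6]; torsions += d[6:] (degrees, wrapped)
static void genome_step(const Genome& g, const std::vector<double>& d,
                        Genome& out) {
  out = g;
  out.t[0] += d[0]; out.t[1] += d[1]; out.t[2] += d[2];
  Quat dq = q_from_rotvec(d[3], d[4], d[5]);
  out.q = q_mul(dq, g.q);
  q_normalize(out.q);
  for (size_t k = 0; k < g.tor.size(); ++k) out.tor[k] = wrap_deg(g.tor[k] + d[6 + k]);
}

// Solis-Wets on the genome: single-sided proposals x + bias + rho*scale*N(0,1),
// accepted on strict improvement; bias <- 0.2*bias + 0.4*dx on success,
// bias <- 0.5*bias on failure; rho doubles after max_consec consecutive
// successes, halves after max_consec consecutive failures; stops when
// rho < rho_min or the evaluation budget is exhausted.
static int solis_wets_genome(Genome& g, double& energy, Scorer& S,
                             const std::vector<double>& scales, long budget,
                             const SwParams& sw, Xoshiro& rng) {
  int dim = (int)scales.size();
  std::vector<double> bias(dim, 0.0), d(dim);
  double rho = sw.rho0;
  int succ = 0, fail = 0;
  long used = 0;
  Genome cand;
  while (used < budget && rho >= sw.rho_min) {
    for (int k = 0; k < dim; ++k) d[k] = bias[k] + rho * scales[k] * rng.norm();
    genome_step(g, d, cand);
    double ce = S.score(cand);
    ++used;
    if (ce < energy) {
      g = cand;
      energy = ce;
      for (int k = 0; k < dim; ++k) bias[k] = 0.2 * bias[k] + 0.4 * d[k];
      ++succ; fail = 0;
      if (succ >= sw.max_consec) { rho *= 2.0; succ = 0; }
    } else {
      for (int k = 0; k < dim; ++k) bias[k] *= 0.5;
      ++fail; succ = 0;
      if (fail >= sw.max_consec) { rho *= 0.5; fail = 0; }
    }
  }
  return (int)used;
}

// Generic-vector Solis-Wets with an R callback scorer; same update rules,
// plain addition in gene space. Serves direct use and the 1-D surrogate.
// [[Rcpp::export]]
List cpp_solis_wets_vec(NumericVector start, Function score_fn,
                        NumericVector scales, int budget, double seed,
                        double rho0, double rho_min, int max_consec) {
  int dim = start.size();
  std::vector<double> x(start.begin(), start.end());
  std::vector<double> bias(dim, 0.0), d(dim), cand(dim);
  Xoshiro rng((uint64_t)seed);
  double energy = as<double>(score_fn(NumericVector(x.begin(), x.end())));
  double rho = rho0;
  int succ = 0, fail = 0, used = 0;
  while (used < budget && rho >= rho_min) {
    for (int k = 0; k < dim; ++k) {
      double sc = scales.size() == 1 ? scales[0] : scales[k];
      d[k] = bias[k] + rho * sc * rng.norm();
      cand[k] = x[k] + d[k];
    }
    double ce = as<double>(score_fn(NumericVector(cand.begin(), cand.end())));
    ++used;
    if (ce < energy) {
      x = cand;
      energy = ce;
      for (int k = 0; k < dim; ++k) bias[k] = 0.2 * bias[k] + 0.4 * d[k];
      ++succ; fail = 0;
      if (succ >= max_consec) { rho *= 2.0; succ = 0; }
    } else {
      for (int k = 0; k < dim; ++k) bias[k] *= 0.5;
      ++fail; succ = 0;
      if (fail >= max_consec) { rho *= 0.5; fail = 0; }
    }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["energy"] = energy, _["evals"] = used);
}

// ---------------------------------------------------------------------------
// The Lamarckian genetic algorithm run
// ---------------------------------------------------------------------------

// rank-proportional parent pick: weight = rank with the best individual
// holding the largest rank
static int pick_parent(const std::vector<int>& order_desc,
                       const std::vector<double>& cumw, double total,
                       Xoshiro& rng) {
  double u = rng.unif() * total;
  int lo = 0, hi = (int)cumw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] < u) lo = mid + 1; else hi = mid;
  }
  return order_desc[lo];
}

// [[Rcpp::export]]
List cpp_run_lga(NumericMatrix coords, NumericVector charges,
                 IntegerVector type_idx, IntegerVector root_idx, List edges,
                 List pairs, List aff_maps, List emap, List dmap,
                 List control, double seed) {
  Ligand L = ligand_from_args(coords, charges, type_idx, root_idx, edges, pairs);
  Scorer S;
  S.L = &L;
  S.aff = maps_from_list(aff_maps);
  S.em = map_from_list(emap);
  S.dm = map_from_list(dmap);
  S.evals = 0;

  const int popsize = as<int>(control["ga_popsize"]);
  const long eval_budget = as<double>(control["ga_num_evals"]);
  const long gen_budget = as<double>(control["ga_num_generations"]);
  const double ls_freq = as<double>(control["ls_frequency"]);
  const double cross_rate = as<double>(control["crossover_rate"]);
  const double mut_rate = as<double>(control["mutation_rate"]);
  const double mut_trans = as<double>(control["mutation_scale_translation"]);
  const double mut_quat = as<double>(control["mutation_scale_orientation"]);
  const double mut_tor = as<double>(control["mutation_scale_torsion"]);
  const int sw_max_its = as<int>(control["sw_max_its"]);
  SwParams sw;
  sw.rho0 = as<double>(control["sw_rho0"]);
  sw.rho_min = as<double>(control["sw_rho_min"]);
  sw.max_consec = as<int>(control["sw_max_consec"]);
  NumericVector box_lo = control["box_lo"], box_hi = control["box_hi"];
  if (popsize < 1) stop("ga_popsize must be >= 1");

  const int ntor = (int)L.edges.size();
  const int ngenes = 4 + ntor;  // tx, ty, tz, orientation, torsions
  std::vector<double> sw_scales(6 + ntor);
  sw_scales[0] = sw_scales[1] = sw_scales[2] = as<double>(control["sw_scale_translation"]);
  sw_scales[3] = sw_scales[4] = sw_scales[5] = as<double>(control["sw_scale_orientation"]);
  for (int k = 0; k < ntor; ++k) sw_scales[6 + k] = as<double>(control["sw_scale_torsion"]);

  Xoshiro rng((uint64_t)seed);

  // initial population: translation uniform in the box, orientation uniform
  // on the quaternion sphere, torsions uniform in (-180, 180]
  std::vector<Genome> pop(popsize);
  std::vector<double> energy(popsize);
  for (int i = 0; i < popsize; ++i) {
    Genome g;
    for (int a = 0; a < 3; ++a)
      g.t[a] = box_lo[a] + rng.unif() * (box_hi[a] - box_lo[a]);
    g.q = q_random(rng);
    g.tor.resize(ntor);
    for (int k = 0; k < ntor; ++k) g.tor[k] = 180.0 - 360.0 * rng.unif();
    pop[i] = g;
    energy[i] = S.score(g);
  }

  Genome best_g = pop[0];
  double best_e = energy[0];
  for (int i = 1; i < popsize; ++i)
    if (energy[i] < best_e) { best_e = energy[i]; best_g = pop[i]; }

  std::vector<double> log_gen, log_evals, log_best, log_mean;
  double mean0 = 0;
  for (int i = 0; i < popsize; ++i) mean0 += energy[i];
  log_gen.push_back(0); log_evals.push_back((double)S.evals);
  log_best.push_back(best_e); log_mean.push_back(mean0 / popsize);

  long gens = 0;
  std::vector<Genome> newpop(popsize);
  std::vector<double> newenergy(popsize);
  std::vector<int> order_desc(popsize);
  std::vector<double> cumw(popsize);

  while (gens < gen_budget && S.evals < eval_budget) {
    // rank weights: sort indices by energy descending (worst first);
    // ties broken by lower index first so ordering is fully deterministic
    for (int i = 0; i < popsize; ++i) order_desc[i] = i;
    std::stable_sort(order_desc.begin(), order_desc.end(),
                     [&](int a, int b) { return energy[a] > energy[b]; });
    double total = 0;
    for (int i = 0; i < popsize; ++i) { total += (double)(i + 1); cumw[i] = total; }

    // elitism: best individual survives unchanged, energy carried over
    int elite = 0;
    for (int i = 1; i < popsize; ++i) if (energy[i] < energy[elite]) elite = i;
    newpop[0] = pop[elite];
    newenergy[0] = energy[elite];

    int filled = 1;
    while (filled < popsize) {
      int pa = pick_parent(order_desc, cumw, total, rng);
      int pb = pick_parent(order_desc, cumw, total, rng);
      Genome c1 = pop[pa], c2 = pop[pb];
      if (rng.unif() < cross_rate) {
        // two-point crossover at gene boundaries
        int cut1 = (int)(rng.unif() * (ngenes + 1));
        int cut2 = (int)(rng.unif() * (ngenes + 1));
        if (cut1 > cut2) std::swap(cut1, cut2);
        for (int gidx = cut1; gidx < cut2; ++gidx) {
          if (gidx < 3) std::swap(c1.t[gidx], c2.t[gidx]);
          else if (gidx == 3) std::swap(c1.q, c2.q);
          else std::swap(c1.tor[gidx - 4], c2.tor[gidx - 4]);
        }
      }
      for (int child = 0; child < 2 && filled < popsize; ++child) {
        Genome& c = child == 0 ? c1 : c2;
        // per-gene Cauchy mutation
        for (int gidx = 0; gidx < ngenes; ++gidx) {
          if (rng.unif() < mut_rate) {
            if (gidx < 3) {
              c.t[gidx] += mut_trans * rng.cauchy();
            } else if (gidx == 3) {
              double ax = rng.norm(), ay = rng.norm(), az = rng.norm();
              double ang = mut_quat * rng.cauchy();
              Quat dq = q_from_axis_angle(ax, ay, az, ang);
              c.q = q_mul(dq, c.q);
              q_normalize(c.q);
            } else {
              c.tor[gidx - 4] = wrap_deg(c.tor[gidx - 4] + mut_tor * rng.cauchy());
            }
          }
        }
        newpop[filled] = c;
        newenergy[filled] = S.score(c);
        ++filled;
      }
    }

    // Lamarckian local search with write-back of improved genomes
    for (int i = 0; i < popsize; ++i) {
      if (rng.unif() < ls_freq) {
        long room = eval_budget - S.evals;
        if (room <= 0) continue;
        long budget = sw_max_its < room ? sw_max_its : room;
        solis_wets_genome(newpop[i], newenergy[i], S, sw_scales, budget, sw, rng);
      }
    }

    pop.swap(newpop);
    energy.swap(newenergy);
    for (int i = 0; i < popsize; ++i)
      if (energy[i] < best_e) { best_e = energy[i]; best_g = pop[i]; }
    ++gens;

    double mean = 0;
    for (int i = 0; i < popsize; ++i) mean += energy[i];
    log_gen.push_back((double)gens);
    log_evals.push_back((double)S.evals);
    log_best.push_back(best_e);
    log_mean.push_back(mean / popsize);
  }

  std::vector<double> X, Y, Z;
  apply_genome(L, best_g, X, Y, Z);
  NumericMatrix best_coords(L.natoms, 3);
  for (int a = 0; a < L.natoms; ++a) {
    best_coords(a, 0) = X[a]; best_coords(a, 1) = Y[a]; best_coords(a, 2) = Z[a];
  }
  int nlog = (int)log_gen.size();
  NumericMatrix genlog(nlog, 4);
  for (int r = 0; r < nlog; ++r) {
    genlog(r, 0) = log_gen[r]; genlog(r, 1) = log_evals[r];
    genlog(r, 2) = log_best[r]; genlog(r, 3) = log_mean[r];
  }
  colnames(genlog) = CharacterVector::create("generation", "evals", "best", "mean");
  return List::create(
      _["best_translation"] = NumericVector::create(best_g.t[0], best_g.t[1], best_g.t[2]),
      _["best_quaternion"] = NumericVector::create(best_g.q.w, best_g.q.x, best_g.q.y, best_g.q.z),
      _["best_torsions"] = NumericVector(best_g.tor.begin(), best_g.tor.end()),
      _["best_energy"] = best_e, _["best_coords"] = best_coords,
      _["generations_done"] = (double)gens, _["evals_used"] = (double)S.evals,
      _["genlog"] = genlog);
}

// [[Rcpp::export]]
NumericVector cpp_rng_stream(double seed, int n, std::string kind) {
  // exposed for determinism tests and the R-level uses that must share the
  // package's portable generator
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (kind == "unif") out[i] = rng.unif();
    else if (kind == "norm") out[i] = rng.norm();
    else out[i] = rng.cauchy();
  }
  return out;
}
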