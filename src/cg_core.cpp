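// Core of the reduced coarse-grained DNA model and its Monte Carlo engines.
//
// One bead per nucleotide. Energy terms (all in kT):
//   bond      0.5 * kbond * (r - r0)^2 between consecutive beads of a chain
//   bending   0.5 * kbend * theta^2 at each interior bead (3-body)
//   excluded  WCA (truncated-shifted LJ, purely repulsive), capped at ecap
//   screened  Yukawa amp * (exp(-r/lD)/r - shift), truncated-shifted at el_cut
//   hybrid    square well of depth hyb_eps for designed arm<->site pairs only
//
// Distances use the minimum-image convention in a periodic cubic box.
// All pair indices at this interface are 0-based.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double kbond, r0, kbend, sigma, eps_ev, ecap;
  double el_amp, lambdaD, el_cut, hyb_eps, hyb_range;
  bool bend_on, ev_on, el_on;
  // derived
  double rc2_ev, sig2, el_cut2, el_shift, hyb2;
};

Params parse_params(const List& p) {
  Params P;
  P.kbond = as<double>(p["bond_k"]);
  P.r0 = as<double>(p["bond_r0"]);
  P.kbend = as<double>(p["bend_k"]);
  P.sigma = as<double>(p["ev_sigma"]);
  P.eps_ev = as<double>(p["ev_epsilon"]);
  P.ecap = as<double>(p["ev_cap"]);
  P.el_amp = as<double>(p["el_amp"]);
  P.lambdaD = as<double>(p["debye_length"]);
  P.el_cut = as<double>(p["el_cutoff"]);
  P.hyb_eps = as<double>(p["hyb_epsilon"]);
  P.hyb_range = as<double>(p["hyb_range"]);
  P.bend_on = as<bool>(p["bend_on"]);
  P.ev_on = as<bool>(p["ev_on"]);
  P.el_on = as<bool>(p["el_on"]);
  double rc = std::pow(2.0, 1.0 / 6.0) * P.sigma;
  P.rc2_ev = rc * rc;
  P.sig2 = P.sigma * P.sigma;
  P.el_cut2 = P.el_cut * P.el_cut;
  P.el_shift = std::exp(-P.el_cut / P.lambdaD) / P.el_cut;
  P.hyb2 = P.hyb_range * P.hyb_range;
  return P;
}

inline double min_img(double d, double L) { return d - L * std::nearbyint(d / L); }
inline double wrap0(double x, double L) { return x - L * std::floor(x / L); }

struct System {
  int n;
  double L;
  std::vector<double> x, y, z;          // wrapped coordinates
  std::vector<int> chain;               // contiguous 0-based chain ids
  Params P;
  std::unordered_set<int64_t> wells;    // designed hybridizing pairs
  std::vector<std::pair<int, int>> extp, ligp;
  bool shortcut;                        // only bonds+wells interact
  std::vector<std::vector<int>> nbr;    // candidate partners in shortcut mode

  inline int64_t key(int i, int j) const {
    int a = i < j ? i : j, b = i < j ? j : i;
    return (int64_t)a * (int64_t)n + b;
  }
  inline bool bonded(int i, int j) const {
    return chain[i] == chain[j] && std::abs(i - j) == 1;
  }
  inline bool is_well(int i, int j) const {
    return wells.find(key(i, j)) != wells.end();
  }

  double dist2(double xi, double yi, double zi, double xj, double yj, double zj) const {
    double dx = min_img(xi - xj, L), dy = min_img(yi - yj, L), dz = min_img(zi - zj, L);
    return dx * dx + dy * dy + dz * dz;
  }

  // pair energy between beads i, j with i at (xi,yi,zi), j at its stored position
  double pair_e(int i, int j, double xi, double yi, double zi,
                double xj, double yj, double zj) const {
    double r2 = dist2(xi, yi, zi, xj, yj, zj);
    if (bonded(i, j)) {
      double r = std::sqrt(r2);
      double d = r - P.r0;
      return 0.5 * P.kbond * d * d;
    }
    double e = 0.0;
    if (P.ev_on && r2 < P.rc2_ev) {
      if (r2 < 0.25 * P.sig2) {
        e += P.ecap;
      } else {
        double s6 = P.sig2 / r2;
        s6 = s6 * s6 * s6;
        double w = 4.0 * P.eps_ev * (s6 * s6 - s6) + P.eps_ev;
        e += (w > P.ecap) ? P.ecap : w;
      }
    }
    if (P.el_on && r2 < P.el_cut2) {
      double r = std::sqrt(r2);
      if (r < 0.05) r = 0.05;  // cap the 1/r divergence
      e += P.el_amp * (std::exp(-r / P.lambdaD) / r - P.el_shift);
    }
    if (P.hyb_eps != 0.0 && r2 < P.hyb2 && is_well(i, j)) e -= P.hyb_eps;
    return e;
  }

  double pair_e_cur(int i, int j) const {
    return pair_e(i, j, x[i], y[i], z[i], x[j], y[j], z[j]);
  }

  // angle energy centred at bead c (requires both neighbours in the same chain)
  bool has_angle(int c) const {
    return c > 0 && c < n - 1 && chain[c - 1] == chain[c] && chain[c] == chain[c + 1];
  }
  double angle_e(double ax, double ay, double az, double bx, double by, double bz,
                 double cx, double cy, double cz) const {
    double ux = min_img(bx - ax, L), uy = min_img(by - ay, L), uz = min_img(bz - az, L);
    double vx = min_img(cx - bx, L), vy = min_img(cy - by, L), vz = min_img(cz - bz, L);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu <= 0 || nv <= 0) return 0.0;
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    return 0.5 * P.kbend * th * th;
  }
  double angle_e_cur(int c) const {
    return angle_e(x[c - 1], y[c - 1], z[c - 1], x[c], y[c], z[c],
                   x[c + 1], y[c + 1], z[c + 1]);
  }

  void build(const NumericMatrix& pos, const IntegerVector& chain_id, double box,
             const Params& pp, const IntegerMatrix& ext, const IntegerMatrix& lig) {
    n = pos.nrow();
    L = box;
    P = pp;
    x.resize(n); y.resize(n); z.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = wrap0(pos(i, 0), L);
      y[i] = wrap0(pos(i, 1), L);
      z[i] = wrap0(pos(i, 2), L);
    }
    chain.assign(chain_id.begin(), chain_id.end());
    extp.clear(); ligp.clear(); wells.clear();
    for (int k = 0; k < ext.nrow(); ++k) {
      extp.emplace_back(ext(k, 0), ext(k, 1));
      wells.insert(key(ext(k, 0), ext(k, 1)));
    }
    for (int k = 0; k < lig.nrow(); ++k) {
      ligp.emplace_back(lig(k, 0), lig(k, 1));
      wells.insert(key(lig(k, 0), lig(k, 1)));
    }
    shortcut = !P.ev_on && !P.el_on;
    if (shortcut) {
      nbr.assign(n, {});
      for (int i = 0; i < n; ++i) {
        if (i > 0 && chain[i - 1] == chain[i]) nbr[i].push_back(i - 1);
        if (i < n - 1 && chain[i + 1] == chain[i]) nbr[i].push_back(i + 1);
      }
      for (auto& pr : extp) { nbr[pr.first].push_back(pr.second); nbr[pr.second].push_back(pr.first); }
      for (auto& pr : ligp) { nbr[pr.first].push_back(pr.second); nbr[pr.second].push_back(pr.first); }
      for (auto& v : nbr) {  // a pair may be both bonded and designed: count it once
        std::sort(v.begin(), v.end());
        v.erase(std::unique(v.begin(), v.end()), v.end());
      }
    }
  }

  double arm_dist(const std::vector<std::pair<int, int>>& prs) const {
    double best = R_PosInf;
    for (auto& pr : prs) {
      double r2 = dist2(x[pr.first], y[pr.first], z[pr.first],
                        x[pr.second], y[pr.second], z[pr.second]);
      if (r2 < best) best = r2;
    }
    return std::sqrt(best);
  }
};

int discretize_cpp(double d, const std::vector<double>& edges) {
  int q = 0;
  for (size_t i = 1; i < edges.size(); ++i) {
    if (d >= edges[i]) q = (int)i; else break;
  }
  return q;
}

// Linked-cell neighbour search over the short-ranged nonbonded terms.
// Bonded pairs are handled separately (bonds can stretch beyond the
// nonbonded cutoff). Falls back to full scans when the box holds fewer
// than 3 cells per side.
struct CellList {
  bool active = false;
  int nc = 0;
  double cellsz = 0, L = 0;
  std::vector<std::vector<int>> cells;
  std::vector<int> cellof;

  int coord(double x) const {
    int c = (int)std::floor(x / cellsz);
    if (c >= nc) c = nc - 1;
    if (c < 0) c = 0;
    return c;
  }
  int idx(double x, double y, double z) const {
    return (coord(x) * nc + coord(y)) * nc + coord(z);
  }
  void build(double box, double rc, const System& S) {
    L = box;
    int n_per_side = (int)std::floor(box / rc);
    active = n_per_side >= 3;
    if (!active) return;
    nc = n_per_side;
    cellsz = box / nc;
    cells.assign((size_t)nc * nc * nc, {});
    cellof.assign(S.n, -1);
    for (int i = 0; i < S.n; ++i) {
      int c = idx(S.x[i], S.y[i], S.z[i]);
      cellof[i] = c;
      cells[c].push_back(i);
    }
  }
  void move_bead(int i, double x, double y, double z) {
    if (!active) return;
    int c = idx(x, y, z);
    if (c == cellof[i]) return;
    auto& v = cells[cellof[i]];
    for (size_t k = 0; k < v.size(); ++k) {
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
    }
    cells[c].push_back(i);
    cellof[i] = c;
  }
  template <typename F>
  void gather(double x, double y, double z, F&& fn) const {
    int cx = coord(wrap0(x, L)), cy = coord(wrap0(y, L)), cz = coord(wrap0(z, L));
    for (int dx = -1; dx <= 1; ++dx) {
      int ix = (cx + dx + nc) % nc;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = (cy + dy + nc) % nc;
        for (int dz = -1; dz <= 1; ++dz) {
          int iz = (cz + dz + nc) % nc;
          for (int j : cells[(ix * nc + iy) * nc + iz]) fn(j);
        }
      }
    }
  }
};

struct Engine {
  System S;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> U{0.0, 1.0};
  double dtrans, drot;
  int cap;
  // neighbour search
  CellList cl;
  double rc_max = 0;
  std::vector<int> stamp;
  int stamp_ctr = 0;
  std::vector<int> cand;
  // umbrella
  std::vector<double> edges;
  int nq;
  std::vector<double> w;  // nq*nq, column-major [qex + nq*qlig]; empty => unbiased
  double dex, dlig;
  int qex, qlig;
  // step workspace
  std::vector<char> inc, op_rel;
  std::vector<double> mx, my, mz;  // moved positions of cluster members
  std::vector<double> ux, uy, uz;  // member positions unwrapped relative to the pivot
  long long n_acc = 0, n_capped = 0;

  void init_op() {
    op_rel.assign(S.n, 0);
    for (auto& pr : S.extp) { op_rel[pr.first] = 1; op_rel[pr.second] = 1; }
    for (auto& pr : S.ligp) { op_rel[pr.first] = 1; op_rel[pr.second] = 1; }
    dex = S.arm_dist(S.extp);
    dlig = S.arm_dist(S.ligp);
    qex = discretize_cpp(dex, edges);
    qlig = discretize_cpp(dlig, edges);
    inc.assign(S.n, 0);
    mx.resize(S.n); my.resize(S.n); mz.resize(S.n);
    ux.resize(S.n); uy.resize(S.n); uz.resize(S.n);
    rc_max = 0;
    if (S.P.ev_on) rc_max = std::max(rc_max, std::sqrt(S.P.rc2_ev));
    if (S.P.el_on) rc_max = std::max(rc_max, S.P.el_cut);
    if (S.P.hyb_eps != 0.0) rc_max = std::max(rc_max, S.P.hyb_range);
    if (!S.shortcut && rc_max > 0) cl.build(S.L, rc_max, S);
    stamp.assign(S.n, -1);
    cand.reserve(64);
  }

  // unique nonbonded+bonded candidates of bead k near up to three probe points
  void collect(int k, const double* p1, const double* p2, const double* p3) {
    cand.clear();
    ++stamp_ctr;
    stamp[k] = stamp_ctr;
    if (k > 0 && S.chain[k - 1] == S.chain[k]) { stamp[k - 1] = stamp_ctr; cand.push_back(k - 1); }
    if (k < S.n - 1 && S.chain[k + 1] == S.chain[k]) { stamp[k + 1] = stamp_ctr; cand.push_back(k + 1); }
    auto take = [&](int j) {
      if (stamp[j] != stamp_ctr) { stamp[j] = stamp_ctr; cand.push_back(j); }
    };
    cl.gather(p1[0], p1[1], p1[2], take);
    if (p2) cl.gather(p2[0], p2[1], p2[2], take);
    if (p3) cl.gather(p3[0], p3[1], p3[2], take);
  }

  inline double wght(int qe, int ql) const { return w.empty() ? 1.0 : w[qe + nq * ql]; }

  // arm distance with bead k virtually at (nx,ny,nz)
  double arm_dist_moved1(const std::vector<std::pair<int, int>>& prs, int k,
                         double nx, double ny, double nz) const {
    double best = R_PosInf;
    for (auto& pr : prs) {
      int i = pr.first, j = pr.second;
      double xi = (i == k) ? nx : S.x[i], yi = (i == k) ? ny : S.y[i], zi = (i == k) ? nz : S.z[i];
      double xj = (j == k) ? nx : S.x[j], yj = (j == k) ? ny : S.y[j], zj = (j == k) ? nz : S.z[j];
      double r2 = S.dist2(xi, yi, zi, xj, yj, zj);
      if (r2 < best) best = r2;
    }
    return std::sqrt(best);
  }

  bool metropolis() {
    int k = (int)(U(rng) * S.n);
    if (k >= S.n) k = S.n - 1;
    double nx = S.x[k] + (2.0 * U(rng) - 1.0) * dtrans;
    double ny = S.y[k] + (2.0 * U(rng) - 1.0) * dtrans;
    double nz = S.z[k] + (2.0 * U(rng) - 1.0) * dtrans;
    double dE = 0.0;
    if (S.shortcut) {
      for (int j : S.nbr[k]) {
        dE += S.pair_e(k, j, nx, ny, nz, S.x[j], S.y[j], S.z[j]) - S.pair_e_cur(k, j);
      }
    } else if (cl.active) {
      double pc[3] = {S.x[k], S.y[k], S.z[k]}, pn[3] = {nx, ny, nz};
      collect(k, pc, pn, nullptr);
      for (int j : cand) {
        dE += S.pair_e(k, j, nx, ny, nz, S.x[j], S.y[j], S.z[j]) - S.pair_e_cur(k, j);
      }
    } else {
      for (int j = 0; j < S.n; ++j) {
        if (j == k) continue;
        dE += S.pair_e(k, j, nx, ny, nz, S.x[j], S.y[j], S.z[j]) - S.pair_e_cur(k, j);
      }
    }
    if (S.P.bend_on) {
      for (int c = k - 1; c <= k + 1; ++c) {
        if (!S.has_angle(c)) continue;
        double ax = S.x[c - 1], ay = S.y[c - 1], az = S.z[c - 1];
        double bx = S.x[c], by = S.y[c], bz = S.z[c];
        double cx = S.x[c + 1], cy = S.y[c + 1], cz = S.z[c + 1];
        double e_old = S.angle_e(ax, ay, az, bx, by, bz, cx, cy, cz);
        if (c - 1 == k) { ax = nx; ay = ny; az = nz; }
        if (c == k) { bx = nx; by = ny; bz = nz; }
        if (c + 1 == k) { cx = nx; cy = ny; cz = nz; }
        dE += S.angle_e(ax, ay, az, bx, by, bz, cx, cy, cz) - e_old;
      }
    }
    double ndex = dex, ndlig = dlig;
    int nqe = qex, nql = qlig;
    if (op_rel[k]) {
      ndex = arm_dist_moved1(S.extp, k, nx, ny, nz);
      ndlig = arm_dist_moved1(S.ligp, k, nx, ny, nz);
      nqe = discretize_cpp(ndex, edges);
      nql = discretize_cpp(ndlig, edges);
    }
    double a = std::exp(-dE) * (wght(nqe, nql) / wght(qex, qlig));
    if (a >= 1.0 || U(rng) < a) {
      S.x[k] = wrap0(nx, S.L); S.y[k] = wrap0(ny, S.L); S.z[k] = wrap0(nz, S.L);
      cl.move_bead(k, S.x[k], S.y[k], S.z[k]);
      dex = ndex; dlig = ndlig; qex = nqe; qlig = nql;
      return true;
    }
    return false;
  }

  // symmetrized VMMC step (Whitelam-Geissler) with early rejection of
  // frustrated links; bending terms across the cluster boundary enter the
  // acceptance as an explicit Boltzmann residual.
  bool vmmc() {
    int s = (int)(U(rng) * S.n);
    if (s >= S.n) s = S.n - 1;
    bool rot = U(rng) < 0.5;
    // Rotations pivot about a bonded neighbour of the seed (chosen uniformly):
    // for point beads a rotation about the seed itself would move nothing, so
    // pivoting on a neighbour turns the move into a crankshaft/pivot of the
    // chain segment recruited through the links. The proposal is symmetric
    // because connectivity is static. Single-bead chains fall back to
    // translations.
    double px = 0, py = 0, pz = 0;
    if (rot) {
      int nb[2], k = 0;
      if (s > 0 && S.chain[s - 1] == S.chain[s]) nb[k++] = s - 1;
      if (s < S.n - 1 && S.chain[s + 1] == S.chain[s]) nb[k++] = s + 1;
      if (k == 0) {
        rot = false;
      } else {
        int c = nb[(k == 2 && U(rng) < 0.5) ? 1 : 0];
        px = S.x[c]; py = S.y[c]; pz = S.z[c];
      }
    }
    double tx = 0, ty = 0, tz = 0;
    double R[3][3];
    if (rot) {
      double ax, ay, az, nrm;
      std::normal_distribution<double> G(0.0, 1.0);
      do { ax = G(rng); ay = G(rng); az = G(rng); nrm = std::sqrt(ax * ax + ay * ay + az * az); } while (nrm < 1e-12);
      ax /= nrm; ay /= nrm; az /= nrm;
      double th = (2.0 * U(rng) - 1.0) * drot;
      double c = std::cos(th), s2 = std::sin(th), C = 1.0 - c;
      R[0][0] = c + ax * ax * C;      R[0][1] = ax * ay * C - az * s2; R[0][2] = ax * az * C + ay * s2;
      R[1][0] = ay * ax * C + az * s2; R[1][1] = c + ay * ay * C;      R[1][2] = ay * az * C - ax * s2;
      R[2][0] = az * ax * C - ay * s2; R[2][1] = az * ay * C + ax * s2; R[2][2] = c + az * az * C;
    } else {
      tx = (2.0 * U(rng) - 1.0) * dtrans;
      ty = (2.0 * U(rng) - 1.0) * dtrans;
      tz = (2.0 * U(rng) - 1.0) * dtrans;
    }
    // Member positions are unwrapped relative to the pivot along the
    // recruitment path (bond and interaction vectors are always short), so
    // the rotation map is a true bijection even when the cluster spans more
    // than half the box; min-imaging the span directly would not be
    // invertible. The reverse map is the transposed rotation / negated
    // translation applied to the same unwrapped coordinates.
    auto join_rel = [&](int j, int parent) {
      if (!rot) { mx[j] = S.x[j] + tx; my[j] = S.y[j] + ty; mz[j] = S.z[j] + tz; return; }
      if (parent < 0) {
        ux[j] = min_img(S.x[j] - px, S.L);
        uy[j] = min_img(S.y[j] - py, S.L);
        uz[j] = min_img(S.z[j] - pz, S.L);
      } else {
        ux[j] = ux[parent] + min_img(S.x[j] - S.x[parent], S.L);
        uy[j] = uy[parent] + min_img(S.y[j] - S.y[parent], S.L);
        uz[j] = uz[parent] + min_img(S.z[j] - S.z[parent], S.L);
      }
      mx[j] = px + R[0][0] * ux[j] + R[0][1] * uy[j] + R[0][2] * uz[j];
      my[j] = py + R[1][0] * ux[j] + R[1][1] * uy[j] + R[1][2] * uz[j];
      mz[j] = pz + R[2][0] * ux[j] + R[2][1] * uy[j] + R[2][2] * uz[j];
    };

    std::fill(inc.begin(), inc.end(), 0);
    std::vector<int> members;
    std::vector<int> queue_;
    std::unordered_set<int64_t> tested;
    struct Failed { int j; double num, den; };
    std::vector<Failed> failed;
    inc[s] = 1;
    members.push_back(s);
    join_rel(s, -1);
    queue_.push_back(s);

    while (!queue_.empty()) {
      int m = queue_.back();
      queue_.pop_back();
      double rvx, rvy, rvz;
      if (!rot) {
        rvx = S.x[m] - tx; rvy = S.y[m] - ty; rvz = S.z[m] - tz;
      } else {
        rvx = px + R[0][0] * ux[m] + R[1][0] * uy[m] + R[2][0] * uz[m];
        rvy = py + R[0][1] * ux[m] + R[1][1] * uy[m] + R[2][1] * uz[m];
        rvz = pz + R[0][2] * ux[m] + R[1][2] * uy[m] + R[2][2] * uz[m];
      }
      auto consider = [&](int j) -> bool {  // returns false on outright rejection
        if (inc[j]) return true;
        int64_t kk = S.key(m, j);
        if (!tested.insert(kk).second) return true;
        double u_cur = S.pair_e_cur(m, j);
        double u_fwd = S.pair_e(m, j, mx[m], my[m], mz[m], S.x[j], S.y[j], S.z[j]);
        double u_rev = S.pair_e(m, j, rvx, rvy, rvz, S.x[j], S.y[j], S.z[j]);
        if (u_cur == u_fwd && u_cur == u_rev) return true;
        double pf = 1.0 - std::exp(-(u_fwd - u_cur));
        double pr = 1.0 - std::exp(-(u_rev - u_cur));
        if (pf < 0.0) pf = 0.0;
        if (pr < 0.0) pr = 0.0;
        if (pf > 0.0 && U(rng) < pf) {
          // link proposed
          if (pr <= 0.0) return false;                      // frustrated
          if (pr < pf && U(rng) >= pr / pf) return false;   // frustrated
          inc[j] = 1;
          if ((int)members.size() + 1 > cap) { ++n_capped; return false; }
          members.push_back(j);
          join_rel(j, m);
          queue_.push_back(j);
        } else if (pf > 0.0 || pr > 0.0) {
          failed.push_back({j, 1.0 - pr, 1.0 - pf});
        }
        return true;
      };
      if (S.shortcut) {
        for (int j : S.nbr[m]) if (!consider(j)) return false;
      } else if (cl.active) {
        double pc[3] = {S.x[m], S.y[m], S.z[m]};
        double pf[3] = {mx[m], my[m], mz[m]};
        double pr2[3] = {rvx, rvy, rvz};
        collect(m, pc, pf, pr2);
        for (int j : cand) if (!consider(j)) return false;
      } else {
        for (int j = 0; j < S.n; ++j) { if (j == m) continue; if (!consider(j)) return false; }
      }
    }

    // With symmetrized link formation the no-link probabilities of pairs that
    // remain at the boundary already carry the pairwise Boltzmann factors.
    // Pairs whose link test failed but whose outer bead was recruited later
    // via another member became internal (their energy is unchanged by the
    // rigid move), so the asymmetry of their test probabilities must be
    // compensated explicitly.
    double lnD = 0.0;
    for (auto& f : failed) {
      if (!inc[f.j]) continue;
      if (f.den <= 0.0 || f.num <= 0.0) return false;
      lnD += std::log(f.num) - std::log(f.den);
    }

    double dE_ang = 0.0;
    if (S.P.bend_on) {
      std::unordered_set<int> seen;
      for (int m : members) {
        for (int c = m - 1; c <= m + 1; ++c) {
          if (!S.has_angle(c)) continue;
          int in0 = inc[c - 1], in1 = inc[c], in2 = inc[c + 1];
          if (in0 && in1 && in2) continue;       // rigid: unchanged
          if (!in0 && !in1 && !in2) continue;
          if (!seen.insert(c).second) continue;
          double ax = in0 ? mx[c - 1] : S.x[c - 1], ay = in0 ? my[c - 1] : S.y[c - 1], az = in0 ? mz[c - 1] : S.z[c - 1];
          double bx = in1 ? mx[c] : S.x[c], by = in1 ? my[c] : S.y[c], bz = in1 ? mz[c] : S.z[c];
          double cx = in2 ? mx[c + 1] : S.x[c + 1], cy = in2 ? my[c + 1] : S.y[c + 1], cz = in2 ? mz[c + 1] : S.z[c + 1];
          dE_ang += S.angle_e(ax, ay, az, bx, by, bz, cx, cy, cz) - S.angle_e_cur(c);
        }
      }
    }

    // order parameter after the move
    auto arm_dist_cluster = [&](const std::vector<std::pair<int, int>>& prs) {
      double best = R_PosInf;
      for (auto& pr : prs) {
        int i = pr.first, j = pr.second;
        double xi = inc[i] ? mx[i] : S.x[i], yi = inc[i] ? my[i] : S.y[i], zi = inc[i] ? mz[i] : S.z[i];
        double xj = inc[j] ? mx[j] : S.x[j], yj = inc[j] ? my[j] : S.y[j], zj = inc[j] ? mz[j] : S.z[j];
        double r2 = S.dist2(xi, yi, zi, xj, yj, zj);
        if (r2 < best) best = r2;
      }
      return std::sqrt(best);
    };
    double ndex = arm_dist_cluster(S.extp);
    double ndlig = arm_dist_cluster(S.ligp);
    int nqe = discretize_cpp(ndex, edges);
    int nql = discretize_cpp(ndlig, edges);

    double lnA = lnD - dE_ang + std::log(wght(nqe, nql)) - std::log(wght(qex, qlig));
    if (lnA < 0.0 && U(rng) >= std::exp(lnA)) return false;
    for (int m : members) {
      S.x[m] = wrap0(mx[m], S.L);
      S.y[m] = wrap0(my[m], S.L);
      S.z[m] = wrap0(mz[m], S.L);
      cl.move_bead(m, S.x[m], S.y[m], S.z[m]);
    }
    dex = ndex; dlig = ndlig; qex = nqe; qlig = nql;
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
List cg_total_energy(NumericMatrix pos, IntegerVector chain_id, double box,
                     List params, IntegerMatrix ext_pairs, IntegerMatrix lig_pairs) {
  System S;
  S.build(pos, chain_id, box, parse_params(params), ext_pairs, lig_pairs);
  double e_bond = 0, e_ang = 0, e_nb = 0, e_hyb = 0;
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      double e = S.pair_e_cur(i, j);
      if (S.bonded(i, j)) {
        e_bond += e;
      } else {
        double r2 = S.dist2(S.x[i], S.y[i], S.z[i], S.x[j], S.y[j], S.z[j]);
        if (S.P.hyb_eps != 0.0 && r2 < S.P.hyb2 && S.is_well(i, j)) {
          e_hyb += -S.P.hyb_eps;
          e -= -S.P.hyb_eps;
        }
        e_nb += e;
      }
    }
  }
  if (S.P.bend_on) {
    for (int c = 1; c < S.n - 1; ++c) {
      if (S.has_angle(c)) e_ang += S.angle_e_cur(c);
    }
  }
  return List::create(_["total"] = e_bond + e_ang + e_nb + e_hyb,
                      _["bond"] = e_bond, _["bend"] = e_ang,
                      _["nonbonded"] = e_nb, _["hybridization"] = e_hyb);
}

// [[Rcpp::export]]
double cg_arm_distance(NumericMatrix pos, double box, IntegerMatrix pairs) {
  double best = R_PosInf;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0), j = pairs(k, 1);
    double dx = min_img(pos(i, 0) - pos(j, 0), box);
    double dy = min_img(pos(i, 1) - pos(j, 1), box);
    double dz = min_img(pos(i, 2) - pos(j, 2), box);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < best) best = r2;
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
List cg_run_sampler(NumericMatrix pos, IntegerVector chain_id, double box,
                    List params, IntegerMatrix ext_pairs, IntegerMatrix lig_pairs,
                    NumericVector edges, Nullable<NumericMatrix> weights,
                    List move, int n_steps, int n_equil, int stride,
                    double seed, int engine) {
  Engine E;
  E.S.build(pos, chain_id, box, parse_params(params), ext_pairs, lig_pairs);
  E.edges.assign(edges.begin(), edges.end());
  E.nq = (int)E.edges.size();
  if (weights.isNotNull()) {
    NumericMatrix wm(weights);
    if (wm.nrow() != E.nq || wm.ncol() != E.nq)
      stop("weight table must be %d x %d to match the bin table", E.nq, E.nq);
    E.w.assign(wm.begin(), wm.end());
    for (double v : E.w) if (!(v > 0)) stop("umbrella weights must all be positive");
  }
  E.dtrans = as<double>(move["max_translation"]);
  E.drot = as<double>(move["max_rotation"]);
  E.cap = as<int>(move["cluster_size_cap"]);
  E.rng.seed((uint64_t)seed);
  E.init_op();

  int total = n_equil + n_steps;
  NumericMatrix hist(E.nq, E.nq);
  int n_rec = (n_steps > 0 && stride > 0) ? (n_steps + stride - 1) / stride : 0;
  IntegerVector tq_ex(n_rec), tq_lig(n_rec);
  NumericVector tree2(n_rec);  // squared end-to-end distance of the first chain
  int last0 = 0;
  while (last0 + 1 < E.S.n && chain_id[last0 + 1] == chain_id[0]) ++last0;
  int rec = 0;
  for (int step = 0; step < total; ++step) {
    bool acc = (engine == 1) ? E.vmmc() : E.metropolis();
    if (acc) ++E.n_acc;
    if (step >= n_equil) {
      hist(E.qex, E.qlig) += 1.0;
      int k = step - n_equil;
      if (stride > 0 && k % stride == 0) {
        tq_ex[rec] = E.qex; tq_lig[rec] = E.qlig;
        tree2[rec] = E.S.dist2(E.S.x[0], E.S.y[0], E.S.z[0],
                               E.S.x[last0], E.S.y[last0], E.S.z[last0]);
        ++rec;
      }
    }
  }
  NumericMatrix out_pos(E.S.n, 3);
  for (int i = 0; i < E.S.n; ++i) {
    out_pos(i, 0) = E.S.x[i]; out_pos(i, 1) = E.S.y[i]; out_pos(i, 2) = E.S.z[i];
  }
  return List::create(
      _["positions"] = out_pos, _["hist"] = hist,
      _["traj_qex"] = tq_ex, _["traj_qlig"] = tq_lig, _["traj_ree2"] = tree2,
      _["accepted"] = (double)E.n_acc, _["capped"] = (double)E.n_capped,
      _["n_steps"] = (double)total, _["n_sampled"] = (double)n_steps,
      _["d_ex"] = E.dex, _["d_lig"] = E.dlig,
      _["q_ex"] = E.qex, _["q_lig"] = E.qlig);
}
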