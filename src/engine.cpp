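// Random-walk engine: periodic helix-angle-rotated substrate queries and the
// membrane-interacting walker loop.  All lengths in micrometres, times in ms.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// counter-style RNG: one xoshiro256++ stream per walker, seeded by
// splitmix64 from (global seed, walker id) so results are independent of
// execution order.

static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG {
  uint64_t s[4];
  void init(uint64_t seed, uint64_t id) {
    uint64_t x = seed * 0x9E3779B97f4A7C15ULL ^ (id + 1) * 0xD1B54A32D192ED03ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---------------------------------------------------------------------------
// substrate geometry

struct Sub {
  int npoly = 0;
  std::vector<std::vector<double>> vx, vy;  // vertices, CCW, open
  std::vector<double> bx0, bx1, by0, by1;   // per-polygon bboxes
  double Lx = 1, Ly = 1, Lz = 1, icd = 0, ha = 0;  // ha: rad per um depth
  bool half_shift = false;
  int gnx = 1, gny = 1;
  double gdx = 1, gdy = 1;
  std::vector<std::vector<int>> grid;       // candidate polygons per cell
  // workspace for candidate gathering
  mutable std::vector<int> stamp;
  mutable int stamp_ctr = 0;
  mutable std::vector<int> cand;
};

static Sub build_sub(const List& sl) {
  Sub S;
  List polys = sl["polys"];
  S.npoly = polys.size();
  S.Lx = as<double>(sl["Lx"]); S.Ly = as<double>(sl["Ly"]);
  S.Lz = as<double>(sl["Lz"]); S.icd = as<double>(sl["icd"]);
  S.ha = as<double>(sl["ha_rad_per_um"]);
  S.half_shift = as<bool>(sl["half_shift"]);
  S.vx.resize(S.npoly); S.vy.resize(S.npoly);
  S.bx0.resize(S.npoly); S.bx1.resize(S.npoly);
  S.by0.resize(S.npoly); S.by1.resize(S.npoly);
  for (int i = 0; i < S.npoly; ++i) {
    NumericMatrix m = polys[i];           // 2 x n
    int n = m.ncol();
    S.vx[i].resize(n); S.vy[i].resize(n);
    double a0 = R_PosInf, a1 = R_NegInf, b0 = R_PosInf, b1 = R_NegInf;
    for (int k = 0; k < n; ++k) {
      S.vx[i][k] = m(0, k); S.vy[i][k] = m(1, k);
      a0 = std::min(a0, m(0, k)); a1 = std::max(a1, m(0, k));
      b0 = std::min(b0, m(1, k)); b1 = std::max(b1, m(1, k));
    }
    S.bx0[i] = a0; S.bx1[i] = a1; S.by0[i] = b0; S.by1[i] = b1;
  }
  double target = std::sqrt(S.Lx * S.Ly / std::max(1, S.npoly));
  S.gnx = std::max(1, (int)std::floor(S.Lx / target));
  S.gny = std::max(1, (int)std::floor(S.Ly / target));
  S.gdx = S.Lx / S.gnx; S.gdy = S.Ly / S.gny;
  S.grid.assign((size_t)S.gnx * S.gny, {});
  for (int i = 0; i < S.npoly; ++i) {
    int i0 = std::max(0, (int)std::floor((S.bx0[i] - 1e-9) / S.gdx));
    int i1 = std::min(S.gnx - 1, (int)std::floor((S.bx1[i] + 1e-9) / S.gdx));
    int j0 = std::max(0, (int)std::floor((S.by0[i] - 1e-9) / S.gdy));
    int j1 = std::min(S.gny - 1, (int)std::floor((S.by1[i] + 1e-9) / S.gdy));
    for (int gj = j0; gj <= j1; ++gj)
      for (int gi = i0; gi <= i1; ++gi)
        S.grid[(size_t)gj * S.gnx + gi].push_back(i);
  }
  S.stamp.assign(S.npoly, -1);
  S.cand.reserve(16);
  return S;
}

static inline double wrapd(double x, double L) {
  // avoids fmod (symbol rebased in recent glibc; floor keeps us portable)
  double r = x - L * std::floor(x / L);
  return (r >= L) ? r - L : r;
}

// even-odd point-in-polygon, edges count as outside (measure zero)
static inline bool pip(const Sub& S, int i, double px, double py) {
  if (px < S.bx0[i] || px > S.bx1[i] || py < S.by0[i] || py > S.by1[i])
    return false;
  const std::vector<double>& X = S.vx[i];
  const std::vector<double>& Y = S.vy[i];
  int n = X.size();
  bool inside = false;
  for (int a = 0, b = n - 1; a < n; b = a++) {
    if ((Y[a] > py) != (Y[b] > py)) {
      double xc = X[a] + (py - Y[a]) / (Y[b] - Y[a]) * (X[b] - X[a]);
      if (px < xc) inside = !inside;
    }
  }
  return inside;
}

// polygon containing local (u, v), or -1 for ECS
static inline int locate_local(const Sub& S, double u, double v) {
  int gi = std::min(S.gnx - 1, std::max(0, (int)std::floor(u / S.gdx)));
  int gj = std::min(S.gny - 1, std::max(0, (int)std::floor(v / S.gdy)));
  const std::vector<int>& cc = S.grid[(size_t)gj * S.gnx + gi];
  for (int idx : cc) if (pip(S, idx, u, v)) return idx;
  return -1;
}

struct Frame {
  double cth, sth;   // rotation of this block row about Y
  double zshift;     // half-block shift of this column
  int row, bx;
};

// global -> local (block) coordinates for a point whose row/column are known
static inline void to_local(const Sub& S, const Frame& F,
                            double x, double y, double z,
                            double& u, double& v, double& w_un) {
  double xl = F.cth * x - F.sth * z;
  double zl = F.sth * x + F.cth * z;
  u = xl - F.bx * S.Lx;
  v = y - F.row * S.Ly;
  w_un = zl + F.zshift;
}

// compartment of a global point
static inline int locate_global(const Sub& S, const double p[3]) {
  if (S.npoly == 0) return -1;
  int row = (int)std::floor(p[1] / S.Ly);
  double th = S.ha * row * S.Ly;
  double cth = std::cos(th), sth = std::sin(th);
  double xl = cth * p[0] - sth * p[2];
  int bx = (int)std::floor(xl / S.Lx);
  double u = xl - bx * S.Lx;
  double v = p[1] - row * S.Ly;
  return locate_local(S, u, v);
}

struct Hit {
  bool found = false;
  double t = -1;          // parameter along the query segment
  double pos[3];          // global hit position
  double n[3];            // global unit normal (outward of the cell wall,
                          // or +/- local z for caps)
  int kind = 0;           // 0 sarcolemma, 1 ICD
  int from = -1, to = -1; // compartments before/after (-1 = ECS)
};

// gather polygons whose bbox intersects [u0,u1]x[v0,v1]
static inline void gather(const Sub& S, double u0, double u1,
                          double v0, double v1) {
  if (u0 > u1) std::swap(u0, u1);
  if (v0 > v1) std::swap(v0, v1);
  int i0 = std::max(0, (int)std::floor((u0 - 1e-9) / S.gdx));
  int i1 = std::min(S.gnx - 1, (int)std::floor((u1 + 1e-9) / S.gdx));
  int j0 = std::max(0, (int)std::floor((v0 - 1e-9) / S.gdy));
  int j1 = std::min(S.gny - 1, (int)std::floor((v1 + 1e-9) / S.gdy));
  S.cand.clear();
  ++S.stamp_ctr;
  for (int gj = j0; gj <= j1; ++gj)
    for (int gi = i0; gi <= i1; ++gi)
      for (int idx : S.grid[(size_t)gj * S.gnx + gi])
        if (S.stamp[idx] != S.stamp_ctr) {
          S.stamp[idx] = S.stamp_ctr;
          S.cand.push_back(idx);
        }
}

// earliest membrane crossing along p0 -> p1; t in (teps, 1]
static bool first_hit(const Sub& S, const double p0[3], const double p1[3],
                      Hit& out) {
  if (S.npoly == 0) return false;
  const double teps = 1e-12;
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};

  // piece boundaries from block-row (Y) crossings
  double tcuts[16];
  int ncut = 0;
  tcuts[ncut++] = 0.0;
  if (d[1] != 0) {
    int r0 = (int)std::floor(p0[1] / S.Ly);
    int r1 = (int)std::floor(p1[1] / S.Ly);
    int lo = std::min(r0, r1), hi = std::max(r0, r1);
    for (int k = lo + 1; k <= hi && ncut < 14; ++k) {
      double t = (k * S.Ly - p0[1]) / d[1];
      if (t > teps && t < 1.0) tcuts[ncut++] = t;
    }
    if (d[1] < 0) std::sort(tcuts + 1, tcuts + ncut);
  }
  tcuts[ncut++] = 1.0;

  for (int ip = 0; ip + 1 < ncut; ++ip) {
    double ta = tcuts[ip], tb = tcuts[ip + 1];
    if (tb - ta < teps) continue;
    double tm = 0.5 * (ta + tb);
    double ym = p0[1] + tm * d[1];
    int row = (int)std::floor(ym / S.Ly);
    double th = S.ha * row * S.Ly;
    double cth = std::cos(th), sth = std::sin(th);
    // rotated coordinates at the piece endpoints (linear in t)
    double Ax = p0[0] + ta * d[0], Ay = p0[1] + ta * d[1], Az = p0[2] + ta * d[2];
    double Bx = p0[0] + tb * d[0], By = p0[1] + tb * d[1], Bz = p0[2] + tb * d[2];
    double xlA = cth * Ax - sth * Az, zlA = sth * Ax + cth * Az;
    double xlB = cth * Bx - sth * Bz, zlB = sth * Bx + cth * Bz;

    // sub-split at X-block column boundaries (shift parity changes)
    double scuts[16];
    int nsc = 0;
    scuts[nsc++] = 0.0;
    double dxl = xlB - xlA;
    if (dxl != 0) {
      int c0 = (int)std::floor(xlA / S.Lx);
      int c1 = (int)std::floor(xlB / S.Lx);
      int lo = std::min(c0, c1), hi = std::max(c0, c1);
      for (int k = lo + 1; k <= hi && nsc < 14; ++k) {
        double s = (k * S.Lx - xlA) / dxl;
        if (s > 1e-12 && s < 1.0) scuts[nsc++] = s;
      }
      if (dxl < 0) std::sort(scuts + 1, scuts + nsc);
    }
    scuts[nsc++] = 1.0;

    for (int is = 0; is + 1 < nsc; ++is) {
      double sa = scuts[is], sb = scuts[is + 1];
      if (sb - sa < 1e-12) continue;
      double sm = 0.5 * (sa + sb);
      double xlm = xlA + sm * dxl;
      int bx = (int)std::floor(xlm / S.Lx);
      double zsh = (S.half_shift && ((bx % 2 + 2) % 2 == 1)) ? S.Lz / 2 : 0.0;
      // local segment endpoints (s-parameterised over [sa, sb])
      double uA = xlA + sa * dxl - bx * S.Lx;
      double uB = xlA + sb * dxl - bx * S.Lx;
      double vA = (Ay + sa * (By - Ay)) - row * S.Ly;
      double vB = (Ay + sb * (By - Ay)) - row * S.Ly;
      double wA = (zlA + sa * (zlB - zlA)) + zsh;
      double wB = (zlA + sb * (zlB - zlA)) + zsh;

      double best = 2.0;            // local tau in (0, 1]
      int best_poly = -1, best_kind = -1, best_from = -2, best_to = -2;
      double bn[3] = {0, 0, 0};     // local-frame normal

      // side walls: 2-D crossing with polygon edges
      gather(S, uA, uB, vA, vB);
      double du = uB - uA, dv = vB - vA;
      for (int idx : S.cand) {
        const std::vector<double>& X = S.vx[idx];
        const std::vector<double>& Y = S.vy[idx];
        int n = X.size();
        for (int a = 0, b = n - 1; a < n; b = a++) {
          double ex = X[a] - X[b], ey = Y[a] - Y[b];   // edge b->a (CCW)
          double denom = du * ey - dv * ex;
          if (std::fabs(denom) < 1e-300) continue;
          double qx = X[b] - uA, qy = Y[b] - vA;
          double tau = (qx * ey - qy * ex) / denom;
          if (tau <= 1e-12 || tau > 1.0 || tau >= best) continue;
          double mu = (qx * dv - qy * du) / denom;
          // mu along edge b->a
          if (mu < 0.0 || mu > 1.0) continue;
          double elen = std::sqrt(ex * ex + ey * ey);
          if (elen < 1e-300) continue;
          double nu = ey / elen, nv = -ex / elen;     // outward for CCW
          double ddir = du * nu + dv * nv;
          if (std::fabs(ddir) < 1e-300) continue;
          best = tau; best_poly = idx; best_kind = 0;
          if (ddir > 0) { best_from = idx; best_to = -1; }
          else          { best_from = -1;  best_to = idx; }
          bn[0] = nu; bn[1] = nv; bn[2] = 0;
        }
      }

      // end caps: crossings of planes w = k * Lz while inside a cell
      double dw = wB - wA;
      if (dw != 0) {
        int k0 = (int)std::floor(wA / S.Lz);
        int k1 = (int)std::floor(wB / S.Lz);
        int lo = std::min(k0, k1), hi = std::max(k0, k1);
        for (int k = lo + 1; k <= hi; ++k) {
          double tau = (k * S.Lz - wA) / dw;
          if (tau <= 1e-12 || tau > 1.0 || tau >= best) continue;
          double uc = uA + tau * du, vc = vA + tau * dv;
          int idx = locate_local(S, uc, vc);
          if (idx < 0) continue;
          best = tau; best_poly = idx; best_kind = 1;
          best_from = idx; best_to = idx;
          bn[0] = 0; bn[1] = 0; bn[2] = (dw > 0) ? 1.0 : -1.0;
        }
      }

      if (best_poly >= 0) {
        double tau = best;
        double tglob = ta + (sa + tau * (sb - sa)) * (tb - ta);
        if (tglob <= teps) continue;
        if (best_kind == 0) {
          // wall: ICD when within icd_depth of a cap
          double wc = wrapd(wA + tau * dw, S.Lz);
          out.kind = (wc < S.icd || wc > S.Lz - S.icd) ? 1 : 0;
        } else {
          out.kind = 1;
        }
        out.found = true;
        out.t = tglob;
        for (int c = 0; c < 3; ++c) out.pos[c] = p0[c] + tglob * d[c];
        // local normal back to global: x = cth*u' + sth*z', z = -sth*u' + cth*z'
        out.n[0] = cth * bn[0] + sth * bn[2];
        out.n[1] = bn[1];
        out.n[2] = -sth * bn[0] + cth * bn[2];
        out.from = best_from; out.to = best_to;
        return true;
      }
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// membrane-interacting advance of one proposed displacement

struct WalkPar {
  double d_ics, d_ecs, kappa_sarco, kappa_icd, pd_factor;
  int max_substeps;
};

// Advances pos by rem, resolving membrane interactions (hybrid transit
// model: cross with probability p_t, else specular reflection; remaining
// path rescaled by sqrt(D_to/D_from) on diffusivity change).  Returns the
// number of substeps used, or -1 on substep-budget overflow.
static int advance_walker(const Sub& S, const WalkPar& P, RNG& r,
                          double pos[3], double rem[3], int& comp) {
  const double push = 1e-9;
  for (int ss = 0; ss < P.max_substeps; ++ss) {
    double tgt[3] = {pos[0] + rem[0], pos[1] + rem[1], pos[2] + rem[2]};
    Hit h;
    if (!first_hit(S, pos, tgt, h)) {
      pos[0] = tgt[0]; pos[1] = tgt[1]; pos[2] = tgt[2];
      return ss;
    }
    double remlen = std::sqrt(rem[0] * rem[0] + rem[1] * rem[1] +
                              rem[2] * rem[2]);
    double after = (1.0 - h.t) * remlen;
    double ddx = std::fabs((pos[0] - h.pos[0]) * h.n[0] +
                           (pos[1] - h.pos[1]) * h.n[1] +
                           (pos[2] - h.pos[2]) * h.n[2]);
    if (ddx < 1e-6) ddx = 1e-6;
    double kap = (h.kind == 1) ? P.kappa_icd : P.kappa_sarco;
    double pb = 2.0 * kap * ddx / (P.d_ics + 2.0 * kap * ddx);
    bool ecs_to_ics = (h.from < 0 && h.to >= 0);
    double pt = ecs_to_ics ? pb * P.pd_factor : pb;
    double dirv[3] = {rem[0] / remlen, rem[1] / remlen, rem[2] / remlen};
    if (r.unif() < pt) {
      double Dfrom = (h.from >= 0) ? P.d_ics : P.d_ecs;
      double Dto = (h.to >= 0) ? P.d_ics : P.d_ecs;
      double scl = std::sqrt(Dto / Dfrom);
      comp = h.to;
      for (int c = 0; c < 3; ++c) {
        pos[c] = h.pos[c] + push * dirv[c];
        rem[c] = dirv[c] * after * scl;
      }
    } else {
      double dn = dirv[0] * h.n[0] + dirv[1] * h.n[1] + dirv[2] * h.n[2];
      double rv[3];
      for (int c = 0; c < 3; ++c) rv[c] = dirv[c] - 2.0 * dn * h.n[c];
      for (int c = 0; c < 3; ++c) {
        pos[c] = h.pos[c] + push * rv[c];
        rem[c] = rv[c] * after;
      }
    }
    if (after < 1e-12) return ss + 1;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// exported queries

// [[Rcpp::export]]
IntegerVector mw_locate(List sub, NumericMatrix pts) {
  Sub S = build_sub(sub);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    out[i] = locate_global(S, p);
  }
  return out;
}

// [[Rcpp::export]]
List mw_intersect(List sub, NumericVector p0, NumericVector p1) {
  Sub S = build_sub(sub);
  double a[3] = {p0[0], p0[1], p0[2]};
  double b[3] = {p1[0], p1[1], p1[2]};
  Hit h;
  if (!first_hit(S, a, b, h)) {
    return List::create(_["t"] = -1.0);
  }
  double dx = std::fabs((a[0] - h.pos[0]) * h.n[0] +
                        (a[1] - h.pos[1]) * h.n[1] +
                        (a[2] - h.pos[2]) * h.n[2]);
  return List::create(
      _["t"] = h.t,
      _["pos"] = NumericVector::create(h.pos[0], h.pos[1], h.pos[2]),
      _["normal"] = NumericVector::create(h.n[0], h.n[1], h.n[2]),
      _["kind"] = h.kind, _["dx"] = dx,
      _["from"] = h.from, _["to"] = h.to);
}

// [[Rcpp::export]]
List mw_seed_walkers(List sub, int np, NumericVector lo, NumericVector hi,
                     int seed) {
  Sub S = build_sub(sub);
  NumericMatrix pos(np, 3);
  IntegerVector comp(np);
  for (int i = 0; i < np; ++i) {
    RNG r; r.init((uint64_t)seed, (uint64_t)i);
    double p[3];
    for (int c = 0; c < 3; ++c) p[c] = lo[c] + r.unif() * (hi[c] - lo[c]);
    pos(i, 0) = p[0]; pos(i, 1) = p[1]; pos(i, 2) = p[2];
    comp[i] = locate_global(S, p);
  }
  return List::create(_["pos"] = pos, _["comp"] = comp);
}

// Core random walk.  `amp` holds gamma times the per-step mean effective
// gradient at unit Gmax (rad / ms / um per mT/m); the per-walker phase
// integral psi = sum_k amp_k * xmid_k * dt factorises over encoding
// directions, so any (direction, Gmax) phase is Gmax * dot(psi, e_g).
// [[Rcpp::export]]
List mw_run_walk(List sub, int np, int nt, double dt,
                 double d_ics, double d_ecs,
                 double kappa_sarco, double kappa_icd, double pd_factor,
                 int seed, int max_substeps,
                 NumericVector seed_lo, NumericVector seed_hi,
                 NumericVector vox_lo, NumericVector vox_hi,
                 NumericVector amp) {
  if (amp.size() != nt) stop("amp must have length nt");
  Sub S = build_sub(sub);
  NumericMatrix psi(np, 3);
  LogicalVector in_voxel(np);
  IntegerVector comp0(np), comp1(np);
  NumericMatrix fin(np, 3);
  long overflow = 0;
  WalkPar P{d_ics, d_ecs, kappa_sarco, kappa_icd, pd_factor, max_substeps};

  std::vector<double> a(nt);
  for (int k = 0; k < nt; ++k) a[k] = amp[k];

  for (int i = 0; i < np; ++i) {
    RNG r; r.init((uint64_t)seed, (uint64_t)i);
    double pos[3];
    for (int c = 0; c < 3; ++c)
      pos[c] = seed_lo[c] + r.unif() * (seed_hi[c] - seed_lo[c]);
    int comp = locate_global(S, pos);
    comp0[i] = comp;
    double ps[3] = {0, 0, 0};

    for (int k = 0; k < nt; ++k) {
      double prev[3] = {pos[0], pos[1], pos[2]};
      double D = (comp >= 0) ? d_ics : d_ecs;
      double len = std::sqrt(2.0 * D * dt);
      uint64_t bits = r.next();
      double rem[3] = {(bits & 1) ? len : -len,
                       (bits & 2) ? len : -len,
                       (bits & 4) ? len : -len};
      if (advance_walker(S, P, r, pos, rem, comp) < 0) ++overflow;
      if (S.npoly > 0) comp = locate_global(S, pos);
      double w = a[k] * dt * 0.5;
      ps[0] += w * (prev[0] + pos[0]);
      ps[1] += w * (prev[1] + pos[1]);
      ps[2] += w * (prev[2] + pos[2]);
    }
    psi(i, 0) = ps[0]; psi(i, 1) = ps[1]; psi(i, 2) = ps[2];
    fin(i, 0) = pos[0]; fin(i, 1) = pos[1]; fin(i, 2) = pos[2];
    comp1[i] = comp;
    in_voxel[i] = pos[0] >= vox_lo[0] && pos[0] <= vox_hi[0] &&
                  pos[1] >= vox_lo[1] && pos[1] <= vox_hi[1] &&
                  pos[2] >= vox_lo[2] && pos[2] <= vox_hi[2];
  }
  return List::create(_["psi"] = psi, _["in_voxel"] = in_voxel,
                      _["comp_init"] = comp0, _["comp_final"] = comp1,
                      _["final_pos"] = fin, _["overflow"] = (double)overflow);
}

// Single proposed displacement with membrane interactions, exposed for
// tests (deterministic when kappa is 0 or effectively infinite).
// [[Rcpp::export]]
List mw_advance(List sub, NumericVector pos0, NumericVector disp,
                double d_ics, double d_ecs,
                double kappa_sarco, double kappa_icd, double pd_factor,
                int max_substeps, int seed) {
  Sub S = build_sub(sub);
  WalkPar P{d_ics, d_ecs, kappa_sarco, kappa_icd, pd_factor, max_substeps};
  RNG r; r.init((uint64_t)seed, 0);
  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double rem[3] = {disp[0], disp[1], disp[2]};
  int comp = locate_global(S, pos);
  int used = advance_walker(S, P, r, pos, rem, comp);
  if (S.npoly > 0) comp = locate_global(S, pos);
  return List::create(
      _["pos"] = NumericVector::create(pos[0], pos[1], pos[2]),
      _["comp"] = comp,
      _["substeps"] = used,
      _["overflow"] = used < 0);
}
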