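// Off-lattice agent-based core: biased random walks, contact-driven state
// transitions, Gaussian chemokine field, and the tumor radius ODE update.
// The hot loop lives here; the R layer owns configuration, tibbles and plots.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG ------
// PCG32: small, fast, and fully determined by the configured seed, so a
// (config, seed) pair reproduces a trajectory bit-for-bit.
struct Pcg32 {
  uint64_t state, inc;
  explicit Pcg32(uint64_t seed, uint64_t seq = 0x14057b7ef767814fULL) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31));
  }
  double runif() { return std::ldexp((double)next(), -32); }  // [0, 1)
  int rpois(double lambda) {  // Knuth multiplication; influx rates are small
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= runif();
    } while (p > L);
    return k - 1;
  }
  // uniform unit vector by rejection sampling (trig-free)
  void runit(double &ux, double &uy) {
    for (;;) {
      double a = 2.0 * runif() - 1.0, b = 2.0 * runif() - 1.0;
      double n2 = a * a + b * b;
      if (n2 > 1e-12 && n2 <= 1.0) {
        double n = std::sqrt(n2);
        ux = a / n;
        uy = b / n;
        return;
      }
    }
  }
};

enum Kind { A_OFF = 0, A_M = 1, T_IN = 2, T_ACT = 3, TIL_K = 4 };

struct Params {
  double g, k, dt, total_min;
  double influx_apc, influx_t;
  double inner_off, outer_off;
  double act_dist, til_lifespan, field_range;
  int rfc_count;
  double patch_radius, eln_dist;
  double init_radius;
  int init_t, init_apc;
  double sigma, amplitude, k_half;
  int capacity;
  double v_kin[5], v_tact[5];
  bool poisson, t_in_away;
  double record_every;
  uint64_t seed;
};

Params read_params(List cfg) {
  Params p;
  p.g = as<double>(cfg["g"]);
  p.k = as<double>(cfg["k"]);
  p.dt = as<double>(cfg["dt"]);
  p.total_min = as<double>(cfg["total_time_days"]) * 1440.0;
  p.influx_apc = as<double>(cfg["influx_rate_apc"]);
  p.influx_t = as<double>(cfg["influx_rate_t"]);
  p.inner_off = as<double>(cfg["annulus_inner_offset"]);
  p.outer_off = as<double>(cfg["annulus_outer_offset"]);
  p.act_dist = as<double>(cfg["activation_distance"]);
  p.til_lifespan = as<double>(cfg["til_lifespan_min"]);
  p.field_range = as<double>(cfg["tumor_field_range"]);
  p.rfc_count = as<int>(cfg["rfc_count"]);
  p.patch_radius = as<double>(cfg["rfc_patch_radius"]);
  p.eln_dist = as<double>(cfg["tumor_eln_distance"]);
  p.init_radius = as<double>(cfg["initial_radius"]);
  p.init_t = as<int>(cfg["initial_t"]);
  p.init_apc = as<int>(cfg["initial_apc"]);
  p.sigma = as<double>(cfg["gaussian_sigma"]);
  p.amplitude = as<double>(cfg["gaussian_amplitude"]);
  p.k_half = as<double>(cfg["k_half"]);
  p.capacity = as<int>(cfg["apc_m_capacity"]);
  p.v_kin[A_OFF] = as<double>(cfg["apc_off_kinetic_speed"]);
  p.v_tact[A_OFF] = as<double>(cfg["apc_off_tactic_speed"]);
  p.v_kin[A_M] = as<double>(cfg["apc_m_kinetic_speed"]);
  p.v_tact[A_M] = as<double>(cfg["apc_m_tactic_speed"]);
  p.v_kin[T_IN] = p.v_kin[T_ACT] = p.v_kin[TIL_K] = as<double>(cfg["t_kinetic_speed"]);
  p.v_tact[T_IN] = p.v_tact[T_ACT] = p.v_tact[TIL_K] = as<double>(cfg["t_tactic_speed"]);
  p.poisson = as<std::string>(cfg["influx_mode"]) == "poisson";
  p.t_in_away = as<std::string>(cfg["inactive_t_bias"]) == "away_from_tumor";
  p.record_every = as<double>(cfg["record_every"]);
  p.seed = (uint64_t)as<double>(cfg["seed"]);
  return p;
}

struct State {
  std::vector<int> id, kind, act;
  std::vector<double> x, y, age;
  int next_id = 1;
  void add(int kd, double px, double py) {
    id.push_back(next_id++);
    kind.push_back(kd);
    act.push_back(0);
    x.push_back(px);
    y.push_back(py);
    age.push_back(0.0);
  }
  size_t n() const { return id.size(); }
};

struct Rfc {
  std::vector<double> x, y;
  std::vector<char> on;
  int n_on = 0;
};

// Precomputed analytic gradient of the sum-of-Gaussians field on a grid
// covering the ELN patch plus a 5-sigma margin (the field is numerically
// zero beyond that); sources are added incrementally as RFC activate.
struct Grid {
  bool enabled = false;
  double x0, y0, h;
  int nx, ny;
  std::vector<double> gx, gy;
  void init(double cx, double cy, double halfw, double h_) {
    h = h_;
    nx = ny = std::min(2001, (int)std::ceil(2.0 * halfw / h) + 2);
    x0 = cx - halfw;
    y0 = cy - halfw;
    gx.assign((size_t)nx * ny, 0.0);
    gy.assign((size_t)nx * ny, 0.0);
    enabled = true;
  }
  void add_source(double sx, double sy, double A, double sigma) {
    if (!enabled) return;
    double s2 = sigma * sigma;
    for (int j = 0; j < ny; ++j) {
      double py = y0 + j * h;
      for (int i = 0; i < nx; ++i) {
        double px = x0 + i * h;
        double dx = px - sx, dy = py - sy;
        double e = A * std::exp(-(dx * dx + dy * dy) / (2.0 * s2)) / s2;
        size_t idx = (size_t)j * nx + i;
        gx[idx] -= e * dx;
        gy[idx] -= e * dy;
      }
    }
  }
  inline void eval(double px, double py, double &ox, double &oy) const {
    ox = 0.0;
    oy = 0.0;
    if (!enabled) return;
    double fx = (px - x0) / h, fy = (py - y0) / h;
    if (fx < 0 || fy < 0 || fx >= nx - 1 || fy >= ny - 1) return;
    int i = (int)fx, j = (int)fy;
    double tx = fx - i, ty = fy - j;
    size_t a = (size_t)j * nx + i, b = a + 1, c = a + nx, d = c + 1;
    ox = (1 - tx) * (1 - ty) * gx[a] + tx * (1 - ty) * gx[b] +
         (1 - tx) * ty * gx[c] + tx * ty * gx[d];
    oy = (1 - tx) * (1 - ty) * gy[a] + tx * (1 - ty) * gy[b] +
         (1 - tx) * ty * gy[c] + tx * ty * gy[d];
  }
};

// Open-addressing spatial hash with per-step versioning (no reallocation in
// the steady state). Queries (inactive T cells, resting RFC) are inserted
// into their own cell and the 8 neighbours, so each APC^M needs exactly one
// probe of its own cell to see every query within one cell size (>= the
// activation distance).
struct QHash {
  std::vector<int64_t> key;
  std::vector<int> head, ver, ent_item, ent_next;
  int M = 0, cur = 0;
  uint64_t mask = 0;
  void reset(size_t expected) {
    size_t need = 64;
    while (need < 2 * expected + 8) need <<= 1;
    if ((size_t)M < need) {
      M = (int)need;
      key.assign(M, 0);
      head.assign(M, -1);
      ver.assign(M, 0);
      mask = M - 1;
      cur = 0;
    }
    ++cur;
    ent_item.clear();
    ent_next.clear();
  }
  static inline uint64_t hashk(int64_t k) {
    uint64_t z = (uint64_t)k * 0x9E3779B97F4A7C15ULL;
    z ^= z >> 29;
    z *= 0xBF58476D1CE4E5B9ULL;
    z ^= z >> 32;
    return z;
  }
  static inline int64_t pack(int ix, int iy) {
    return ((int64_t)(uint32_t)ix << 32) | (uint32_t)iy;
  }
  inline int slot(int64_t k, bool create) {
    uint64_t i = hashk(k) & mask;
    for (;;) {
      if (ver[i] != cur) {
        if (!create) return -1;
        ver[i] = cur;
        key[i] = k;
        head[i] = -1;
        return (int)i;
      }
      if (key[i] == k) return (int)i;
      i = (i + 1) & mask;
    }
  }
  inline void insert(int64_t k, int item) {
    int s = slot(k, true);
    ent_item.push_back(item);
    ent_next.push_back(head[s]);
    head[s] = (int)ent_item.size() - 1;
  }
};

struct Contact {  // candidate (inactive T, APC^M) pair within activation range
  int t_idx;
  double d2;
  int apc_id, apc_idx;
};

struct Counters {
  double cum_influx_apc = 0, cum_influx_t = 0;
  double cum_til_expired = 0, cum_apc_m_removed = 0;
};

struct Events {  // populated only by the exposed single-step wrapper
  bool collect = false;
  std::vector<int> apc_loaded, rfc_activated, t_activated, til_entered,
      til_expired, apc_removed;
};

struct Workspace {
  QHash hash;
  std::vector<Contact> contacts;
  std::vector<char> dead;
};

// State transitions, applied once per step in the fixed order:
//   (a) antigen loading  (c) RFC activation  (b) T-cell activation
//   (d) TIL entry        (e) ageing + TIL expiry
void do_transitions(const Params &P, double R, State &S, Rfc &F, Grid &G,
                    Workspace &W, Counters &C, Events &E) {
  size_t n = S.n();
  double R2 = R * R;

  // (a) APC^OFF inside the tumor picks up antigen -> APC^M
  for (size_t i = 0; i < n; ++i) {
    if (S.kind[i] == A_OFF && S.x[i] * S.x[i] + S.y[i] * S.y[i] <= R2) {
      S.kind[i] = A_M;
      S.act[i] = 0;
      S.age[i] = 0.0;
      if (E.collect) E.apc_loaded.push_back(S.id[i]);
    }
  }

  // Build the query hash: inactive T cells and resting RFC, replicated into
  // the 3x3 cell neighbourhood. One lookup per APC^M then covers all
  // queries within the activation distance.
  double cs = P.act_dist, cs2 = cs * cs;
  size_t n_tq = 0, n_fq = 0;
  for (size_t i = 0; i < n; ++i)
    if (S.kind[i] == T_IN) ++n_tq;
  for (size_t f = 0; f < F.x.size(); ++f)
    if (!F.on[f]) ++n_fq;
  bool any_apc_m = false;
  for (size_t i = 0; i < n && !any_apc_m; ++i)
    if (S.kind[i] == A_M) any_apc_m = true;

  W.contacts.clear();
  if ((n_tq + n_fq) > 0 && any_apc_m) {
    W.hash.reset(9 * (n_tq + n_fq));
    for (size_t i = 0; i < n; ++i) {
      if (S.kind[i] != T_IN) continue;
      int ix = (int)std::floor(S.x[i] / cs), iy = (int)std::floor(S.y[i] / cs);
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          W.hash.insert(QHash::pack(ix + a, iy + b), (int)i);
    }
    for (size_t f = 0; f < F.x.size(); ++f) {
      if (F.on[f]) continue;
      int ix = (int)std::floor(F.x[f] / cs), iy = (int)std::floor(F.y[f] / cs);
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          W.hash.insert(QHash::pack(ix + a, iy + b), -(int)f - 1);
    }
    // single pass over APC^M: (c) fires immediately, (b) contacts collected
    for (size_t m = 0; m < n; ++m) {
      if (S.kind[m] != A_M) continue;
      int ix = (int)std::floor(S.x[m] / cs), iy = (int)std::floor(S.y[m] / cs);
      int s = W.hash.slot(QHash::pack(ix, iy), false);
      if (s < 0) continue;
      for (int e = W.hash.head[s]; e != -1; e = W.hash.ent_next[e]) {
        int q = W.hash.ent_item[e];
        if (q >= 0) {
          double dx = S.x[q] - S.x[m], dy = S.y[q] - S.y[m];
          double d2 = dx * dx + dy * dy;
          if (d2 <= cs2)
            W.contacts.push_back({q, d2, S.id[m], (int)m});
        } else {
          int f = -q - 1;
          if (!F.on[f]) {
            double dx = F.x[f] - S.x[m], dy = F.y[f] - S.y[m];
            if (dx * dx + dy * dy <= cs2) {
              F.on[f] = 1;  // (c) APC^M contact activates the RFC
              ++F.n_on;
              G.add_source(F.x[f], F.y[f], P.amplitude, P.sigma);
              if (E.collect) E.rfc_activated.push_back(f + 1);
            }
          }
        }
      }
    }
  }

  // (b) each inactive T cell, in id order, is activated by its nearest
  // APC^M within range that still has presentation capacity (ties: lower id)
  W.dead.assign(n, 0);
  if (!W.contacts.empty()) {
    std::sort(W.contacts.begin(), W.contacts.end(),
              [](const Contact &a, const Contact &b) {
                if (a.t_idx != b.t_idx) return a.t_idx < b.t_idx;
                if (a.d2 != b.d2) return a.d2 < b.d2;
                return a.apc_id < b.apc_id;
              });
    int cur_t = -1;
    bool done = false;
    for (const Contact &c : W.contacts) {
      if (c.t_idx != cur_t) {
        cur_t = c.t_idx;
        done = false;
      }
      if (done || S.act[c.apc_idx] >= P.capacity) continue;
      S.kind[c.t_idx] = T_ACT;
      S.age[c.t_idx] = 0.0;
      if (E.collect) E.t_activated.push_back(S.id[c.t_idx]);
      if (++S.act[c.apc_idx] >= P.capacity) {
        W.dead[c.apc_idx] = 1;  // presentation capacity exhausted
        C.cum_apc_m_removed += 1;
        if (E.collect) E.apc_removed.push_back(c.apc_id);
      }
      done = true;
    }
  }

  // (d) activated T cells crossing the tumor boundary become TIL
  for (size_t i = 0; i < n; ++i) {
    if (S.kind[i] == T_ACT && S.x[i] * S.x[i] + S.y[i] * S.y[i] <= R2) {
      S.kind[i] = TIL_K;
      S.age[i] = 0.0;
      if (E.collect) E.til_entered.push_back(S.id[i]);
    }
  }

  // (e) ageing, then TIL expiry
  for (size_t i = 0; i < n; ++i) {
    S.age[i] += P.dt;
    if (S.kind[i] == TIL_K && S.age[i] > P.til_lifespan) {
      W.dead[i] = 1;
      C.cum_til_expired += 1;
      if (E.collect) E.til_expired.push_back(S.id[i]);
    }
  }

  // compact, preserving id order
  size_t w = 0;
  for (size_t i = 0; i < n; ++i) {
    if (W.dead[i]) continue;
    if (w != i) {
      S.id[w] = S.id[i];
      S.kind[w] = S.kind[i];
      S.act[w] = S.act[i];
      S.x[w] = S.x[i];
      S.y[w] = S.y[i];
      S.age[w] = S.age[i];
    }
    ++w;
  }
  S.id.resize(w);
  S.kind.resize(w);
  S.act.resize(w);
  S.x.resize(w);
  S.y.resize(w);
  S.age.resize(w);
}

// one off-lattice walk update for every motile agent; the directed terms are
// summed as a bias vector (clamped to unit norm), then scaled by one uniform
// draw of the tactic distance
void move_cells(const Params &P, double R, State &S, const Grid &G,
                Pcg32 &rng) {
  double outer = R + P.field_range, outer2 = outer * outer;
  size_t n = S.n();
  for (size_t i = 0; i < n; ++i) {
    int kd = S.kind[i];
    double px = S.x[i], py = S.y[i];
    double ux, uy;
    rng.runit(ux, uy);
    double L = rng.runif() * P.v_kin[kd] * P.dt;
    double nx = px + L * ux, ny = py + L * uy;
    double bx = 0, by = 0;
    double r2 = px * px + py * py;
    bool in_field = r2 <= outer2 && r2 > 0;
    if (kd == A_OFF) {
      if (in_field) {
        double r = std::sqrt(r2);
        bx -= px / r;
        by -= py / r;
      }
    } else if (kd == A_M || kd == T_IN) {
      bool away = (kd == A_M) || P.t_in_away;
      if (away && in_field) {
        double r = std::sqrt(r2);
        bx += px / r;
        by += py / r;
      }
      double gxv, gyv;
      G.eval(px, py, gxv, gyv);
      double gm = std::sqrt(gxv * gxv + gyv * gyv);
      if (gm > 0) {
        double s = gm / (gm + P.k_half);
        bx += s * gxv / gm;
        by += s * gyv / gm;
      }
    } else {  // T_ACT, TIL: directed toward the tumor center
      if (in_field) {
        double r = std::sqrt(r2);
        bx -= px / r;
        by -= py / r;
      }
    }
    double bn2 = bx * bx + by * by;
    if (bn2 > 1.0) {
      double bn = std::sqrt(bn2);
      bx /= bn;
      by /= bn;
    }
    if (bn2 > 0) {
      double Lt = rng.runif() * P.v_tact[kd] * P.dt;
      nx += Lt * bx;
      ny += Lt * by;
    }
    S.x[i] = nx;
    S.y[i] = ny;
  }
}

void spawn_annulus(const Params &P, double R, int kd, State &S, Pcg32 &rng) {
  double ri = std::max(0.0, R - P.inner_off), ro = R + P.outer_off;
  double u = rng.runif(), v = rng.runif();
  double r = std::sqrt(ri * ri + u * (ro * ro - ri * ri));
  double th = 6.283185307179586 * v;
  S.add(kd, r * std::cos(th), r * std::sin(th));
}

void init_all(const Params &P, State &S, Rfc &F, Grid &G, Pcg32 &rng) {
  for (int i = 0; i < P.rfc_count; ++i) {
    double r = P.patch_radius * std::sqrt(rng.runif());
    double th = 6.283185307179586 * rng.runif();
    F.x.push_back(P.eln_dist + r * std::cos(th));
    F.y.push_back(r * std::sin(th));
    F.on.push_back(0);
  }
  if (P.rfc_count > 0) {
    double h = std::min(25.0, std::max(2.0, P.sigma / 8.0));
    G.init(P.eln_dist, 0.0, P.patch_radius + 5.0 * P.sigma, h);
  }
  for (int i = 0; i < P.init_apc; ++i)
    spawn_annulus(P, P.init_radius, A_OFF, S, rng);
  for (int i = 0; i < P.init_t; ++i)
    spawn_annulus(P, P.init_radius, T_IN, S, rng);
}

DataFrame agents_df(const State &S) {
  return DataFrame::create(_["id"] = S.id, _["kind"] = S.kind, _["x"] = S.x,
                           _["y"] = S.y, _["age"] = S.age,
                           _["activations"] = S.act);
}

DataFrame rfc_df(const Rfc &F) {
  LogicalVector on(F.on.size());
  for (size_t f = 0; f < F.on.size(); ++f) on[f] = F.on[f] != 0;
  return DataFrame::create(_["x"] = F.x, _["y"] = F.y, _["active"] = on);
}

}  // namespace

// [[Rcpp::export]]
List cpp_init_simulation(List cfg) {
  Params P = read_params(cfg);
  Pcg32 rng(P.seed);
  State S;
  Rfc F;
  Grid G;
  init_all(P, S, F, G, rng);
  return List::create(_["agents"] = agents_df(S), _["rfc"] = rfc_df(F),
                      _["radius"] = P.init_radius);
}

// [[Rcpp::export]]
List cpp_run_simulation(List cfg) {
  Params P = read_params(cfg);
  Pcg32 rng(P.seed);
  State S;
  Rfc F;
  Grid G;
  init_all(P, S, F, G, rng);

  int nsteps = (int)std::llround(P.total_min / P.dt);
  int rec = std::max(1, (int)std::llround(P.record_every / P.dt));
  Workspace W;
  Counters C;
  Events E;  // collect = false: counters only
  double R = P.init_radius;
  double acc_apc = 0.0, acc_t = 0.0;

  int nrec = nsteps / rec + 1;
  std::vector<double> o_time, o_rad;
  std::vector<int> o_aoff, o_am, o_tin, o_tact, o_til, o_ron;
  std::vector<double> o_ciapc, o_cit, o_cexp, o_crem;
  o_time.reserve(nrec);

  auto record = [&](double tmin) {
    int c[5] = {0, 0, 0, 0, 0};
    for (size_t i = 0; i < S.n(); ++i) ++c[S.kind[i]];
    o_time.push_back(tmin);
    o_rad.push_back(R);
    o_aoff.push_back(c[A_OFF]);
    o_am.push_back(c[A_M]);
    o_tin.push_back(c[T_IN]);
    o_tact.push_back(c[T_ACT]);
    o_til.push_back(c[TIL_K]);
    o_ron.push_back(F.n_on);
    o_ciapc.push_back(C.cum_influx_apc);
    o_cit.push_back(C.cum_influx_t);
    o_cexp.push_back(C.cum_til_expired);
    o_crem.push_back(C.cum_apc_m_removed);
  };
  record(0.0);

  for (int step = 1; step <= nsteps; ++step) {
    // influx of fresh APC^OFF then inactive T cells into the annulus
    int na, nt;
    if (P.poisson) {
      na = P.influx_apc > 0 ? rng.rpois(P.influx_apc * P.dt) : 0;
      nt = P.influx_t > 0 ? rng.rpois(P.influx_t * P.dt) : 0;
    } else {
      acc_apc += P.influx_apc * P.dt;
      na = (int)std::floor(acc_apc);
      acc_apc -= na;
      acc_t += P.influx_t * P.dt;
      nt = (int)std::floor(acc_t);
      acc_t -= nt;
    }
    for (int i = 0; i < na; ++i) spawn_annulus(P, R, A_OFF, S, rng);
    for (int i = 0; i < nt; ++i) spawn_annulus(P, R, T_IN, S, rng);
    C.cum_influx_apc += na;
    C.cum_influx_t += nt;

    move_cells(P, R, S, G, rng);
    do_transitions(P, R, S, F, G, W, C, E);

    // Eq.-style radius update from the current TIL count inside the tumor
    int L = 0;
    double R2 = R * R;
    for (size_t i = 0; i < S.n(); ++i)
      if (S.kind[i] == TIL_K && S.x[i] * S.x[i] + S.y[i] * S.y[i] <= R2) ++L;
    R = std::max(0.0, R + (P.g - P.k * (double)L) * P.dt);

    if (step % rec == 0) record(step * P.dt);
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  DataFrame ts = DataFrame::create(
      _["time_min"] = o_time, _["radius_um"] = o_rad,
      _["n_apc_off"] = o_aoff, _["n_apc_m"] = o_am, _["n_t_inactive"] = o_tin,
      _["n_t_active"] = o_tact, _["n_til"] = o_til, _["n_rfc_on"] = o_ron,
      _["cum_influx_apc"] = o_ciapc, _["cum_influx_t"] = o_cit,
      _["cum_til_expired"] = o_cexp, _["cum_apc_m_removed"] = o_crem);
  return List::create(_["timeseries"] = ts, _["final_agents"] = agents_df(S),
                      _["rfc"] = rfc_df(F));
}

// [[Rcpp::export]]
List cpp_transition_cells(IntegerVector id, IntegerVector kind,
                          NumericVector x, NumericVector y, NumericVector age,
                          IntegerVector act, NumericVector rfc_x,
                          NumericVector rfc_y, LogicalVector rfc_on, double R,
                          List cfg) {
  Params P = read_params(cfg);
  State S;
  S.id = std::vector<int>(id.begin(), id.end());
  S.kind = std::vector<int>(kind.begin(), kind.end());
  S.x = std::vector<double>(x.begin(), x.end());
  S.y = std::vector<double>(y.begin(), y.end());
  S.age = std::vector<double>(age.begin(), age.end());
  S.act = std::vector<int>(act.begin(), act.end());
  Rfc F;
  F.x = std::vector<double>(rfc_x.begin(), rfc_x.end());
  F.y = std::vector<double>(rfc_y.begin(), rfc_y.end());
  for (R_xlen_t i = 0; i < rfc_on.size(); ++i) F.on.push_back(rfc_on[i] ? 1 : 0);
  for (auto o : F.on) F.n_on += o;
  Grid G;  // disabled: the field does not enter the transition rules
  Workspace W;
  Counters C;
  Events E;
  E.collect = true;
  do_transitions(P, R, S, F, G, W, C, E);
  LogicalVector on_out(F.on.size());
  for (size_t f = 0; f < F.on.size(); ++f) on_out[f] = F.on[f] != 0;
  return List::create(
      _["agents"] = agents_df(S), _["rfc_on"] = on_out,
      _["events"] = List::create(
          _["apc_loaded"] = wrap(E.apc_loaded),
          _["rfc_activated"] = wrap(E.rfc_activated),
          _["t_activated"] = wrap(E.t_activated),
          _["til_entered"] = wrap(E.til_entered),
          _["til_expired"] = wrap(E.til_expired),
          _["apc_m_removed"] = wrap(E.apc_removed)));
}

// All unordered pairs (i, j), i < j, with ||p_i - p_j|| <= radius.
// method "hash" uses the spatial grid; "brute" is the all-pairs reference.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericVector x, NumericVector y,
                                 double radius, std::string method) {
  R_xlen_t n = x.size();
  double r2 = radius * radius;
  std::vector<int> ai, bj;
  if (method == "brute") {
    for (R_xlen_t i = 0; i < n; ++i)
      for (R_xlen_t j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy <= r2) {
          ai.push_back((int)i + 1);
          bj.push_back((int)j + 1);
        }
      }
  } else {
    QHash H;
    H.reset(9 * (size_t)n);
    double cs = radius > 0 ? radius : 1.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int ix = (int)std::floor(x[i] / cs), iy = (int)std::floor(y[i] / cs);
      // probe own cell for earlier points, then insert replicated
      int s = H.slot(QHash::pack(ix, iy), false);
      if (s >= 0) {
        for (int e = H.head[s]; e != -1; e = H.ent_next[e]) {
          int j = H.ent_item[e];
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= r2) {
            ai.push_back(j + 1);
            bj.push_back((int)i + 1);
          }
        }
      }
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          H.insert(QHash::pack(ix + a, iy + b), (int)i);
    }
  }
  IntegerMatrix out((int)ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) {
    // report with the smaller index first for a canonical ordering
    int a = std::min(ai[k], bj[k]), b = std::max(ai[k], bj[k]);
    out(k, 0) = a;
    out(k, 1) = b;
  }
  return out;
}
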