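// Core engine for the worm-blob agent model: cross-shaped agent geometry,
// contact detection, repellent reaction-diffusion grid, force/torque
// assembly and the two-stage exponential Runge-Kutta step.
//
// Uses R's RNG (via R::runif) so trajectories are reproducible from
// set.seed(); execution is single-threaded and the reduction order over
// agents/pairs is fixed, which is part of the determinism contract.
//
// Contact detection bookkeeping: a spatial hash produces candidate pairs
// (centre distance within d_contact + skin), refreshed only when the
// accumulated motion could invalidate the list; the per-step contact test
// over candidates is exact, so the contact graph is identical to a full
// per-step recomputation.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- params ---

struct Pars {
  double m, c, a, tau, l_a, l_b, alpha, beta, eta;
  double d_R, t_min, t_max, d_C;
  double q1, rho1, rho2, rho3, lam1, lam2, r0;
  double d_A, q2, d_P, d_W, k_W;
  double Dm, Em, kA0, kA1, DA;
  double dt, d_contact, d_touch, r_c, grid_dx, speed_scale;
};

static Pars parse_pars(const List& p) {
  Pars q;
  q.m = p["m"]; q.c = p["c"]; q.a = p["a"]; q.tau = p["tau"];
  q.l_a = p["l_a"]; q.l_b = p["l_b"]; q.alpha = p["alpha"]; q.beta = p["beta"];
  q.eta = p["eta"]; q.d_R = p["d_R"]; q.t_min = p["t_min"]; q.t_max = p["t_max"];
  q.d_C = p["d_C"]; q.q1 = p["q1"]; q.rho1 = p["rho1"]; q.rho2 = p["rho2"];
  q.rho3 = p["rho3"]; q.lam1 = p["lambda1"]; q.lam2 = p["lambda2"];
  q.r0 = p["r0"]; q.d_A = p["d_A"]; q.q2 = p["q2"]; q.d_P = p["d_P"];
  q.d_W = p["d_W"]; q.k_W = p["k_W"]; q.Dm = p["D_mustard"]; q.Em = p["E_mustard"];
  q.kA0 = p["k_A0"]; q.kA1 = p["k_A1"]; q.DA = p["D_A"]; q.dt = p["dt"];
  q.d_contact = p["d_contact"]; q.d_touch = p["d_touch"];
  q.r_c = p["r_c"]; q.grid_dx = p["grid_dx"];
  q.speed_scale = p["speed_scale"];
  return q;
}

// -------------------------------------------------------------- geometry ---

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

static double pt_seg_dist2(double px, double py, double ax, double ay,
                           double bx, double by) {
  double ux = bx - ax, uy = by - ay;
  double L2 = ux * ux + uy * uy;
  double t = L2 > 0.0 ? clamp01(((px - ax) * ux + (py - ay) * uy) / L2) : 0.0;
  double dx = px - (ax + t * ux), dy = py - (ay + t * uy);
  return dx * dx + dy * dy;
}

// minimum squared distance between segments (a1,a2) and (b1,b2)
static double seg_seg_dist2(double a1x, double a1y, double a2x, double a2y,
                            double b1x, double b1y, double b2x, double b2y) {
  double ux = a2x - a1x, uy = a2y - a1y;
  double vx = b2x - b1x, vy = b2y - b1y;
  double wx = a1x - b1x, wy = a1y - b1y;
  double A = ux * ux + uy * uy, B = ux * vx + uy * vy, C = vx * vx + vy * vy;
  double D = ux * wx + uy * wy, E = vx * wx + vy * wy;
  double den = A * C - B * B;
  double s = (den > 1e-30) ? clamp01((B * E - C * D) / den) : 0.0;
  double t = (C > 1e-30) ? clamp01((B * s + E) / C) : 0.0;
  if (A > 1e-30) s = clamp01((B * t - D) / A);
  double dx = (a1x + s * ux) - (b1x + t * vx);
  double dy = (a1y + s * uy) - (b1y + t * vy);
  return dx * dx + dy * dy;
}

static bool point_in_poly(double px, double py,
                          const std::vector<double>& qx,
                          const std::vector<double>& qy) {
  int n = (int)qx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if ((qy[i] > py) != (qy[j] > py)) {
      double xc = qx[i] + (py - qy[i]) / (qy[j] - qy[i]) * (qx[j] - qx[i]);
      if (px < xc) inside = !inside;
    }
  }
  return inside;
}

// first intersection parameter of ray p + t*d (t > 0) with segment (a,b)
static double ray_seg_hit(double px, double py, double dx, double dy,
                          double ax, double ay, double bx, double by) {
  double sx = bx - ax, sy = by - ay;
  double den = dx * sy - dy * sx;
  if (std::fabs(den) < 1e-30) return -1.0;
  double t = ((ax - px) * sy - (ay - py) * sx) / den;
  double u = ((ax - px) * dy - (ay - py) * dx) / den;
  if (t >= 0.0 && u >= 0.0 && u <= 1.0) return t;
  return -1.0;
}

// ---------------------------------------------------------------- agents ---

struct SoA {
  int n;
  std::vector<double> x, y, vx, vy, th, l, zeta, tref;
};

static SoA parse_agents(const NumericMatrix& A) {
  SoA s; s.n = A.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.vx.resize(s.n); s.vy.resize(s.n);
  s.th.resize(s.n); s.l.resize(s.n); s.zeta.resize(s.n); s.tref.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = A(i, 0); s.y[i] = A(i, 1); s.vx[i] = A(i, 2); s.vy[i] = A(i, 3);
    s.th[i] = A(i, 4); s.l[i] = A(i, 5); s.zeta[i] = A(i, 6); s.tref[i] = A(i, 7);
  }
  return s;
}

static NumericMatrix agents_matrix(const SoA& s) {
  NumericMatrix A(s.n, 8);
  for (int i = 0; i < s.n; ++i) {
    A(i, 0) = s.x[i]; A(i, 1) = s.y[i]; A(i, 2) = s.vx[i]; A(i, 3) = s.vy[i];
    A(i, 4) = s.th[i]; A(i, 5) = s.l[i]; A(i, 6) = s.zeta[i]; A(i, 7) = s.tref[i];
  }
  colnames(A) = CharacterVector::create("x", "y", "vx", "vy", "theta", "l",
                                        "zeta", "t_refresh");
  return A;
}

// cross arms of one agent: 4 segments sharing the centre.
// endpoints: 0 head (+l along heading), 1 tail (-a), 2/3 laterals (+-a)
struct Arms {
  double cx, cy;
  double ex[4], ey[4];
  double minx[4], maxx[4], miny[4], maxy[4]; // per-arm AABB
  double reach;                              // max(l, a)
};

static void make_arms(double x, double y, double th, double l, double a,
                      Arms& A) {
  double ct = std::cos(th), st = std::sin(th);
  A.cx = x; A.cy = y;
  A.ex[0] = x + l * ct; A.ey[0] = y + l * st;
  A.ex[1] = x - a * ct; A.ey[1] = y - a * st;
  A.ex[2] = x - a * st; A.ey[2] = y + a * ct;
  A.ex[3] = x + a * st; A.ey[3] = y - a * ct;
  for (int k = 0; k < 4; ++k) {
    A.minx[k] = std::min(x, A.ex[k]); A.maxx[k] = std::max(x, A.ex[k]);
    A.miny[k] = std::min(y, A.ey[k]); A.maxy[k] = std::max(y, A.ey[k]);
  }
  A.reach = std::max(l, a);
}

// ------------------------------------------------------------------ walls ---

struct Env {
  int nw;
  std::vector<double> wx1, wy1, wx2, wy2, wang;   // segments + tangent angle
  std::vector<double> wminx, wmaxx, wminy, wmaxy; // per-segment AABB
  std::vector<double> px, py;                     // boundary polygon
  int npeg;
  std::vector<double> pgx, pgy;
  double peg_r;
  bool has_walls;
};

static Env parse_env(const List& e) {
  Env v;
  NumericMatrix W = e["walls"];
  v.nw = W.nrow();
  v.has_walls = v.nw > 0;
  v.wx1.resize(v.nw); v.wy1.resize(v.nw); v.wx2.resize(v.nw); v.wy2.resize(v.nw);
  v.wang.resize(v.nw);
  for (int i = 0; i < v.nw; ++i) {
    v.wx1[i] = W(i, 0); v.wy1[i] = W(i, 1); v.wx2[i] = W(i, 2); v.wy2[i] = W(i, 3);
    double ang = std::atan2(v.wy2[i] - v.wy1[i], v.wx2[i] - v.wx1[i]);
    ang -= M_PI * std::floor(ang / M_PI);   // tangent angle mod pi, in [0, pi)
    v.wang[i] = ang;
    v.wminx.push_back(std::min(v.wx1[i], v.wx2[i]));
    v.wmaxx.push_back(std::max(v.wx1[i], v.wx2[i]));
    v.wminy.push_back(std::min(v.wy1[i], v.wy2[i]));
    v.wmaxy.push_back(std::max(v.wy1[i], v.wy2[i]));
  }
  if (v.has_walls) {
    NumericMatrix P = e["poly"];
    v.px.resize(P.nrow()); v.py.resize(P.nrow());
    for (int i = 0; i < P.nrow(); ++i) { v.px[i] = P(i, 0); v.py[i] = P(i, 1); }
  }
  NumericMatrix G = e["pegs"];
  v.npeg = G.nrow();
  v.pgx.resize(v.npeg); v.pgy.resize(v.npeg);
  for (int i = 0; i < v.npeg; ++i) { v.pgx[i] = G(i, 0); v.pgy[i] = G(i, 1); }
  v.peg_r = as<double>(e["peg_r"]);
  return v;
}

// ------------------------------------------------------------------ field ---

struct Grid {
  int nx, ny;
  double x0, y0, dx;
  bool mustard;
  std::vector<double> a;      // column-major a[ix + nx*iy], cell centres
  std::vector<char> mask;     // 1 = cell centre inside the arena domain
  std::vector<int> ghosts;    // outside cells adjacent to inside cells
  inline double at(int ix, int iy) const { return a[ix + (std::size_t)nx * iy]; }
  inline bool in(int ix, int iy) const { return mask[ix + (std::size_t)nx * iy] != 0; }
};

static void find_ghosts(Grid& g) {
  g.ghosts.clear();
  for (int iy = 0; iy < g.ny; ++iy)
    for (int ix = 0; ix < g.nx; ++ix) {
      if (g.in(ix, iy)) continue;
      bool adj = (ix > 0 && g.in(ix - 1, iy)) || (ix + 1 < g.nx && g.in(ix + 1, iy)) ||
                 (iy > 0 && g.in(ix, iy - 1)) || (iy + 1 < g.ny && g.in(ix, iy + 1));
      if (adj) g.ghosts.push_back(ix + g.nx * iy);
    }
}

static Grid parse_grid(const List& f) {
  Grid g;
  g.nx = as<int>(f["nx"]); g.ny = as<int>(f["ny"]);
  g.x0 = as<double>(f["x0"]); g.y0 = as<double>(f["y0"]);
  g.dx = as<double>(f["dx"]); g.mustard = as<bool>(f["mustard"]);
  NumericMatrix A = f["a"];   // nx x ny
  g.a.assign(A.begin(), A.end());
  LogicalMatrix M = f["mask"];
  g.mask.resize(g.a.size());
  for (std::size_t k = 0; k < g.a.size(); ++k) g.mask[k] = M[k] ? 1 : 0;
  find_ghosts(g);
  return g;
}

static NumericMatrix grid_matrix(const Grid& g) {
  NumericMatrix A(g.nx, g.ny);
  std::copy(g.a.begin(), g.a.end(), A.begin());
  return A;
}

// one explicit Euler step of the repellent field: decay + grid-native
// 5-point Laplacian with zero-flux (mirror) boundaries at the domain
// walls and the grid edges, then a per-agent deposit of kA1*dt into the
// containing cell. The repellent cannot diffuse through arena walls: an
// out-of-domain neighbour mirrors the centre cell. After the update,
// "ghost" cells just outside the domain get the mean of their inside
// neighbours so interpolation/gradients sampled near a wall see no
// artificial step. Agents outside the grid deposit nothing.
static void field_step(Grid& g, const std::vector<double>& ax,
                       const std::vector<double>& ay, const Pars& p) {
  int nx = g.nx, ny = g.ny;
  static std::vector<double> buf;
  buf.resize(g.a.size());
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      std::size_t k = ix + (std::size_t)nx * iy;
      double c = g.a[k];
      if (!g.mask[k]) { buf[k] = c; continue; }
      double n = (iy + 1 < ny && g.in(ix, iy + 1)) ? g.at(ix, iy + 1) : c;
      double s = (iy > 0 && g.in(ix, iy - 1)) ? g.at(ix, iy - 1) : c;
      double e = (ix + 1 < nx && g.in(ix + 1, iy)) ? g.at(ix + 1, iy) : c;
      double w = (ix > 0 && g.in(ix - 1, iy)) ? g.at(ix - 1, iy) : c;
      double lap = n + s + e + w - 4.0 * c;
      buf[k] = c + p.dt * (-p.kA0 * c + p.DA * lap);
    }
  }
  g.a.swap(buf);
  for (std::size_t i = 0; i < ax.size(); ++i) {
    int ix = (int)std::floor((ax[i] - g.x0) / g.dx);
    int iy = (int)std::floor((ay[i] - g.y0) / g.dx);
    if (ix >= 0 && ix < nx && iy >= 0 && iy < ny)
      g.a[ix + (std::size_t)nx * iy] += p.kA1 * p.dt;
  }
  // ghost fill for sampling continuity at walls
  for (std::size_t m = 0; m < g.ghosts.size(); ++m) {
    int k = g.ghosts[m];
    int ix = k % nx, iy = k / nx;
    double sum = 0.0; int cnt = 0;
    if (ix > 0 && g.in(ix - 1, iy)) { sum += g.at(ix - 1, iy); ++cnt; }
    if (ix + 1 < nx && g.in(ix + 1, iy)) { sum += g.at(ix + 1, iy); ++cnt; }
    if (iy > 0 && g.in(ix, iy - 1)) { sum += g.at(ix, iy - 1); ++cnt; }
    if (iy + 1 < ny && g.in(ix, iy + 1)) { sum += g.at(ix, iy + 1); ++cnt; }
    if (cnt > 0) g.a[k] = sum / cnt;
  }
}

// central-difference gradient of a_s at a node, one-sided at edges (SI 1/m)
static inline void node_grad(const Grid& g, int ix, int iy,
                             double& gx, double& gy) {
  int nx = g.nx, ny = g.ny;
  if (ix > 0 && ix < nx - 1) gx = (g.at(ix + 1, iy) - g.at(ix - 1, iy)) / (2 * g.dx);
  else if (ix == 0 && nx > 1) gx = (g.at(1, iy) - g.at(0, iy)) / g.dx;
  else if (ix == nx - 1 && nx > 1) gx = (g.at(nx - 1, iy) - g.at(nx - 2, iy)) / g.dx;
  else gx = 0.0;
  if (iy > 0 && iy < ny - 1) gy = (g.at(ix, iy + 1) - g.at(ix, iy - 1)) / (2 * g.dx);
  else if (iy == 0 && ny > 1) gy = (g.at(ix, 1) - g.at(ix, 0)) / g.dx;
  else if (iy == ny - 1 && ny > 1) gy = (g.at(ix, ny - 1) - g.at(ix, ny - 2)) / g.dx;
  else gy = 0.0;
}

// bilinear sample of a_s and its gradient at (x, y); false when outside
static bool sample_as(const Grid& g, double x, double y,
                      double& A, double& gx, double& gy) {
  double u = (x - g.x0) / g.dx - 0.5;
  double v = (y - g.y0) / g.dx - 0.5;
  if (u < -0.5 || v < -0.5 || u > g.nx - 0.5 || v > g.ny - 0.5) {
    A = 0.0; gx = 0.0; gy = 0.0;
    return false;
  }
  int ix = (int)std::floor(u), iy = (int)std::floor(v);
  if (ix < 0) ix = 0;
  if (ix > g.nx - 2) ix = g.nx - 2;
  if (iy < 0) iy = 0;
  if (iy > g.ny - 2) iy = g.ny - 2;
  if (g.nx == 1) ix = 0;
  if (g.ny == 1) iy = 0;
  double fx = clamp01(u - ix), fy = clamp01(v - iy);
  int ix1 = std::min(ix + 1, g.nx - 1), iy1 = std::min(iy + 1, g.ny - 1);
  double a00 = g.at(ix, iy), a10 = g.at(ix1, iy);
  double a01 = g.at(ix, iy1), a11 = g.at(ix1, iy1);
  A = (1 - fx) * (1 - fy) * a00 + fx * (1 - fy) * a10 +
      (1 - fx) * fy * a01 + fx * fy * a11;
  double g00x, g00y, g10x, g10y, g01x, g01y, g11x, g11y;
  node_grad(g, ix, iy, g00x, g00y); node_grad(g, ix1, iy, g10x, g10y);
  node_grad(g, ix, iy1, g01x, g01y); node_grad(g, ix1, iy1, g11x, g11y);
  gx = (1 - fx) * (1 - fy) * g00x + fx * (1 - fy) * g10x +
       (1 - fx) * fy * g01x + fx * fy * g11x;
  gy = (1 - fx) * (1 - fy) * g00y + fx * (1 - fy) * g10y +
       (1 - fx) * fy * g01y + fx * fy * g11y;
  return true;
}

// full stimulus A = a_s + a_m and its gradient (mustard analytic, with x
// measured in grid units)
static void sample_stimulus(const Grid& g, const Pars& p, double x, double y,
                            double& A, double& gx, double& gy) {
  sample_as(g, x, y, A, gx, gy);
  if (g.mustard) {
    double am = p.Dm * std::exp(p.Em * x / p.grid_dx);
    A += am;
    gx += p.Em / p.grid_dx * am;
  }
}

// ------------------------------------------------------------ interaction ---

static inline double bracket(double d, const Pars& p) {
  double s = std::max(d, 0.1 * p.r0) / p.r0;
  if (p.lam1 == 1.0 && p.lam2 == 2.0) {    // table defaults: no pow needed
    double inv = 1.0 / s;
    return inv * (1.0 - p.rho2 * inv);
  }
  return std::pow(s, -p.lam1) - p.rho2 * std::pow(s, -p.lam2);
}

static inline double sat(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return 0.0;
  return 0.5 * (1.0 + x);
}

static inline double wrap_pi(double th) {
  // wrap to (-pi, pi] (floor-based; avoids fmod)
  double x = th - 2.0 * M_PI * std::floor((th + M_PI) / (2.0 * M_PI));
  if (x <= -M_PI) x = M_PI;
  return x;
}

// per-agent wall interaction record, frozen over a step's two stages
struct WallRec {
  bool contact;   // any arm within d_contact of a wall (or centre outside)
  double fx, fy;  // precomputed wall spring force k_W (r_W - r)
  double s2u, c2u; // sin/cos of twice the nearest wall tangent angle
};

// per-step context (contact graph etc.), frozen across the two RK stages
struct Ctx {
  std::vector<int> eI, eJ;             // undirected contact edges
  std::vector<int> N;                  // contact counts
  std::vector<std::vector<int> > pegs; // contacted pegs per agent
  std::vector<int> nearpeg;            // nearest contacted peg (-1 if none)
  std::vector<WallRec> wall;
  std::vector<double> G;               // activity, cached per step
};

struct Breakdown {
  std::vector<double> propx, propy, pairx, pairy, pegx, pegy, wallx, wally;
  std::vector<double> wrand, wchem, wnem, wpeg, wwall;
  void init(int n) {
    propx.assign(n, 0); propy.assign(n, 0); pairx.assign(n, 0); pairy.assign(n, 0);
    pegx.assign(n, 0); pegy.assign(n, 0); wallx.assign(n, 0); wally.assign(n, 0);
    wrand.assign(n, 0); wchem.assign(n, 0); wnem.assign(n, 0);
    wpeg.assign(n, 0); wwall.assign(n, 0);
  }
};

// assemble all explicit force/torque terms at the given stage state.
// fx,fy hold the full Eq-2 right-hand side (propulsion + pair + peg +
// wall); W the full Eq-3 right-hand side. With bk non-null the per-term
// breakdown is stored as well.
static void assemble(const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<double>& vx, const std::vector<double>& vy,
                     const std::vector<double>& th, const std::vector<double>& l,
                     const std::vector<double>& zeta,
                     const Ctx& ctx, const Env& env, const Grid& grid,
                     const Pars& p,
                     std::vector<double>& fx, std::vector<double>& fy,
                     std::vector<double>& W, Breakdown* bk) {
  int n = (int)x.size();
  fx.assign(n, 0.0); fy.assign(n, 0.0); W.assign(n, 0.0);
  static std::vector<double> ct, st, c2, s2;
  ct.resize(n); st.resize(n); c2.resize(n); s2.resize(n);
  for (int i = 0; i < n; ++i) {
    ct[i] = std::cos(th[i]); st[i] = std::sin(th[i]);
    c2[i] = ct[i] * ct[i] - st[i] * st[i];   // cos 2th
    s2[i] = 2.0 * ct[i] * st[i];             // sin 2th
  }
  // per-agent terms
  for (int i = 0; i < n; ++i) {
    double G = ctx.G[i];
    // propulsion (speed_scale repairs the table's eta units; vignette)
    double fp = p.speed_scale * p.eta * G * l[i];
    double px_ = fp * ct[i], py_ = fp * st[i];
    fx[i] += px_; fy[i] += py_;
    if (bk) { bk->propx[i] = px_; bk->propy[i] = py_; }
    // random torque (piecewise-constant drive, frozen across stages)
    double wr = p.d_R * zeta[i];
    W[i] += wr;
    if (bk) bk->wrand[i] = wr;
    // chemotactic torque: sin(thbar - th) with thbar = arg(-grad A)
    double A, gx, gy;
    sample_stimulus(grid, p, x[i], y[i], A, gx, gy);
    double wc = 0.0;
    double gn = std::sqrt(gx * gx + gy * gy);
    if (gn > 0.0 && G > 0.0)
      wc = p.d_C * G * (gx * st[i] - gy * ct[i]) / gn;
    W[i] += wc;
    if (bk) bk->wchem[i] = wc;
    // peg interactions (forces summed over contacted pegs; alignment to
    // the nearest contacted peg only)
    const std::vector<int>& pg = ctx.pegs[i];
    for (std::size_t k = 0; k < pg.size(); ++k) {
      int q = pg[k];
      double dx = env.pgx[q] - x[i], dy = env.pgy[q] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      double fxx = -p.q2 * vx[i], fyy = -p.q2 * vy[i];
      if (d > 0.0) {
        double fr = p.rho3 * (l[i] - p.a) * bracket(d, p) / d;
        fxx += fr * dx; fyy += fr * dy;
      }
      fx[i] += fxx; fy[i] += fyy;
      if (bk) { bk->pegx[i] += fxx; bk->pegy[i] += fyy; }
    }
    if (ctx.nearpeg[i] >= 0) {
      int q = ctx.nearpeg[i];
      double dx = env.pgx[q] - x[i], dy = env.pgy[q] - y[i];
      double d2 = dx * dx + dy * dy;
      double wp = 0.0;
      if (d2 > 0.0) {
        double s2ip = 2.0 * dx * dy / d2, c2ip = (dx * dx - dy * dy) / d2;
        wp = p.d_P * (s2ip * c2[i] - c2ip * s2[i]);
      }
      W[i] += wp;
      if (bk) bk->wpeg[i] = wp;
    }
    // wall interactions (record frozen at step start)
    const WallRec& wrc = ctx.wall[i];
    fx[i] += wrc.fx; fy[i] += wrc.fy;
    if (bk) { bk->wallx[i] = wrc.fx; bk->wally[i] = wrc.fy; }
    if (wrc.contact) {
      double ww = p.d_W * (wrc.s2u * c2[i] - wrc.c2u * s2[i]);
      W[i] += ww;
      if (bk) bk->wwall[i] = ww;
    }
  }
  // pair interactions: one pass over undirected edges; the translational
  // terms are exactly antisymmetric, the nematic torque has each agent's
  // own activity/elongation prefactor
  int ne = (int)ctx.eI.size();
  for (int k = 0; k < ne; ++k) {
    int i = ctx.eI[k], j = ctx.eJ[k];
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double d = std::sqrt(dx * dx + dy * dy);
    double fxx = p.q1 * (vx[j] - vx[i]);
    double fyy = p.q1 * (vy[j] - vy[i]);
    if (d > 0.0) {
      double fr = p.rho1 * bracket(d, p) / d;
      fxx += fr * dx; fyy += fr * dy;
    }
    fx[i] += fxx; fy[i] += fyy;
    fx[j] -= fxx; fy[j] -= fyy;
    double sd = s2[j] * c2[i] - c2[j] * s2[i];  // sin(2(th_j - th_i))
    double LL = (l[i] - p.a) * (l[j] - p.a);
    double wni = p.d_A * ctx.G[i] * LL * sd;
    double wnj = -p.d_A * ctx.G[j] * LL * sd;
    W[i] += wni; W[j] += wnj;
    if (bk) {
      bk->pairx[i] += fxx; bk->pairy[i] += fyy;
      bk->pairx[j] -= fxx; bk->pairy[j] -= fyy;
      bk->wnem[i] += wni; bk->wnem[j] += wnj;
    }
  }
}

// ----------------------------------------------------- contact detection ---

// spatial-hash candidate pair sweep: all (i, j) with centre-centre
// distance <= thr, found exactly in the 3x3 neighbourhood of cells of
// size thr
static void find_pairs(const std::vector<double>& x,
                       const std::vector<double>& y, double thr,
                       std::vector<int>& ci, std::vector<int>& cj) {
  ci.clear(); cj.clear();
  int n = (int)x.size();
  if (n < 2) return;
  double cell = thr;
  double t2 = thr * thr;
  std::unordered_map<std::int64_t, std::vector<int> > hash;
  hash.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    std::int64_t cx = (std::int64_t)std::floor(x[i] / cell);
    std::int64_t cy = (std::int64_t)std::floor(y[i] / cell);
    hash[(cx << 32) ^ (cy & 0xffffffffLL)].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    std::int64_t cx = (std::int64_t)std::floor(x[i] / cell);
    std::int64_t cy = (std::int64_t)std::floor(y[i] / cell);
    for (std::int64_t ox = -1; ox <= 1; ++ox) {
      for (std::int64_t oy = -1; oy <= 1; ++oy) {
        std::unordered_map<std::int64_t, std::vector<int> >::const_iterator it =
          hash.find(((cx + ox) << 32) ^ ((cy + oy) & 0xffffffffLL));
        if (it == hash.end()) continue;
        const std::vector<int>& cellv = it->second;
        for (std::size_t m = 0; m < cellv.size(); ++m) {
          int j = cellv[m];
          if (j <= i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          if (dx * dx + dy * dy <= t2) {
            ci.push_back(i); cj.push_back(j);
          }
        }
      }
    }
  }
}

// ------------------------------------------------------------- wall prep ---

// clearance grid: conservative lower bound on the distance from anywhere in
// a cell to the nearest wall (distance at the cell centre minus half the
// cell diagonal); lets interior agents skip the wall scan entirely.
// For each field cell: a conservative lower bound on the wall distance
// anywhere in the cell, the nearest wall segment to the cell centre, and
// the circular index window around it that provably contains the nearest
// segment for *any* point in the cell (all segments whose centre distance
// is within d0 + cell diagonal qualify).
static void clearance_grid(const Grid& g, const Env& env,
                           std::vector<double>& clr,
                           std::vector<int>& nearseg,
                           std::vector<int>& winrad) {
  clr.assign(g.a.size(), 1e30);
  nearseg.assign(g.a.size(), 0);
  winrad.assign(g.a.size(), 0);
  if (!env.has_walls) return;
  double half_diag = 0.7071067811865476 * g.dx;
  std::vector<double> dist2(env.nw);
  for (int iy = 0; iy < g.ny; ++iy) {
    for (int ix = 0; ix < g.nx; ++ix) {
      double cx = g.x0 + (ix + 0.5) * g.dx, cy = g.y0 + (iy + 0.5) * g.dx;
      double best = 1e30; int bw = 0;
      for (int w = 0; w < env.nw; ++w) {
        dist2[w] = pt_seg_dist2(cx, cy, env.wx1[w], env.wy1[w],
                                env.wx2[w], env.wy2[w]);
        if (dist2[w] < best) { best = dist2[w]; bw = w; }
      }
      double lim = std::sqrt(best) + 2.0 * half_diag;
      int rad = 0;
      for (int w = 0; w < env.nw; ++w) {
        if (dist2[w] <= lim * lim) {
          int o = std::abs(w - bw);
          o = std::min(o, env.nw - o);       // circular distance
          if (o > rad) rad = o;
        }
      }
      std::size_t k = ix + (std::size_t)g.nx * iy;
      clr[k] = std::sqrt(best) - half_diag;
      nearseg[k] = bw;
      winrad[k] = rad;
    }
  }
}

static double clearance_at(const Grid& g, const std::vector<double>& clr,
                           double x, double y) {
  int ix = (int)std::floor((x - g.x0) / g.dx);
  int iy = (int)std::floor((y - g.y0) / g.dx);
  if (ix < 0 || ix >= g.nx || iy < 0 || iy >= g.ny) return -1.0;
  return clr[ix + (std::size_t)g.nx * iy];
}

// hint < 0: scan all wall segments; otherwise scan the per-cell window
// (exact by construction of clearance_grid)
static void wall_record(const Arms& A, double x, double y, const Env& env,
                        const Pars& p, WallRec& rec, int hint, int rad) {
  rec.contact = false; rec.fx = 0; rec.fy = 0; rec.s2u = 0; rec.c2u = 1;
  if (!env.has_walls) return;
  double best = 1e30; int bw = -1;
  if (hint >= 0 && 2 * rad + 1 < env.nw) {
    for (int o = -rad; o <= rad; ++o) {
      int w = ((hint + o) % env.nw + env.nw) % env.nw;
      double d2 = pt_seg_dist2(x, y, env.wx1[w], env.wy1[w], env.wx2[w], env.wy2[w]);
      // lowest index wins ties (e.g. a shared vertex as nearest point),
      // matching a plain full scan
      if (d2 < best || (d2 == best && w < bw)) { best = d2; bw = w; }
    }
  } else {
    for (int w = 0; w < env.nw; ++w) {
      double d2 = pt_seg_dist2(x, y, env.wx1[w], env.wy1[w], env.wx2[w], env.wy2[w]);
      if (d2 < best) { best = d2; bw = w; }
    }
  }
  double tang = env.wang[bw];
  rec.s2u = std::sin(2.0 * tang); rec.c2u = std::cos(2.0 * tang);
  bool inside = point_in_poly(x, y, env.px, env.py);
  if (!inside) {
    // penetration force back toward the nearest wall point
    double ux = env.wx2[bw] - env.wx1[bw], uy = env.wy2[bw] - env.wy1[bw];
    double L2 = ux * ux + uy * uy;
    double t = L2 > 0 ? clamp01(((x - env.wx1[bw]) * ux + (y - env.wy1[bw]) * uy) / L2) : 0.0;
    double nx = env.wx1[bw] + t * ux, ny = env.wy1[bw] + t * uy;
    rec.fx = p.k_W * (nx - x); rec.fy = p.k_W * (ny - y);
    rec.contact = true;
    return;
  }
  // contact test: any arm within the touch distance of any wall segment
  double thr = p.d_touch, t2 = thr * thr;
  for (int w = 0; w < env.nw && !rec.contact; ++w) {
    for (int k = 0; k < 4; ++k) {
      if (A.minx[k] > env.wmaxx[w] + thr || env.wminx[w] > A.maxx[k] + thr ||
          A.miny[k] > env.wmaxy[w] + thr || env.wminy[w] > A.maxy[k] + thr)
        continue;
      if (seg_seg_dist2(A.cx, A.cy, A.ex[k], A.ey[k],
                        env.wx1[w], env.wy1[w], env.wx2[w], env.wy2[w]) <= t2) {
        // torque aligns to the *nearest* wall segment (already in rec)
        rec.contact = true;
        break;
      }
    }
  }
}

// --------------------------------------------------------------- context ---

// candidate pair store (verlet list over centre distances)
struct Cand {
  std::vector<int> ci, cj;
  double S;                   // global accumulated-motion clock
  double S_rebuild;           // clock value at last candidate-list rebuild
  bool valid;
  Cand() : S(0), S_rebuild(0), valid(false) {}
};

static const double VERLET_SKIN = 2.0e-3; // m

static void refresh_arms(const SoA& s, const Pars& p, std::vector<Arms>& arms) {
  arms.resize(s.n);
  for (int i = 0; i < s.n; ++i)
    make_arms(s.x[i], s.y[i], s.th[i], s.l[i], p.a, arms[i]);
}

static void ensure_candidates(const SoA& s, const Pars& p, Cand& cd) {
  if (!cd.valid || 2.0 * (cd.S - cd.S_rebuild) >= VERLET_SKIN) {
    find_pairs(s.x, s.y, p.d_contact + VERLET_SKIN, cd.ci, cd.cj);
    cd.S_rebuild = cd.S;
    cd.valid = true;
  }
}

static void build_ctx(const SoA& s, const std::vector<Arms>& arms,
                      Cand& cd, const Env& env, const Grid& grid,
                      const std::vector<double>& clr,
                      const std::vector<int>& nearseg,
                      const std::vector<int>& winrad, const Pars& p,
                      Ctx& ctx) {
  int n = s.n;
  // contact edges: centre-centre distance <= d_contact among candidates
  ctx.eI.clear(); ctx.eJ.clear();
  ctx.N.assign(n, 0);
  double t2 = p.d_contact * p.d_contact;
  for (std::size_t k = 0; k < cd.ci.size(); ++k) {
    int i = cd.ci[k], j = cd.cj[k];
    double dx = s.x[j] - s.x[i], dy = s.y[j] - s.y[i];
    if (dx * dx + dy * dy <= t2) {
      ctx.eI.push_back(i); ctx.eJ.push_back(j);
      ctx.N[i]++; ctx.N[j]++;
    }
  }
  // peg contacts
  if ((int)ctx.pegs.size() != n) ctx.pegs.resize(n);
  for (int i = 0; i < n; ++i) ctx.pegs[i].clear();
  ctx.nearpeg.assign(n, -1);
  if (env.npeg > 0) {
    double thr = env.peg_r + p.d_touch, t2 = thr * thr;
    for (int i = 0; i < n; ++i) {
      double bestd = 1e30;
      for (int q = 0; q < env.npeg; ++q) {
        double dx = env.pgx[q] - arms[i].cx, dy = env.pgy[q] - arms[i].cy;
        double lim = arms[i].reach + thr;
        if (dx * dx + dy * dy > lim * lim) continue;
        double dmin2 = 1e30;
        for (int k = 0; k < 4; ++k) {
          double d2 = pt_seg_dist2(env.pgx[q], env.pgy[q],
                                   arms[i].cx, arms[i].cy,
                                   arms[i].ex[k], arms[i].ey[k]);
          if (d2 < dmin2) dmin2 = d2;
        }
        if (dmin2 <= t2) {
          ctx.pegs[i].push_back(q);
          if (dmin2 < bestd) { bestd = dmin2; ctx.nearpeg[i] = q; }
        }
      }
    }
  }
  // wall records
  ctx.wall.assign(n, WallRec());
  if (env.has_walls) {
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor((s.x[i] - grid.x0) / grid.dx);
      int iy = (int)std::floor((s.y[i] - grid.y0) / grid.dx);
      bool ingrid = ix >= 0 && ix < grid.nx && iy >= 0 && iy < grid.ny;
      double cl = ingrid ? clr[ix + (std::size_t)grid.nx * iy] : -1.0;
      if (cl > arms[i].reach + p.d_touch) {
        ctx.wall[i].contact = false; ctx.wall[i].fx = 0; ctx.wall[i].fy = 0;
      } else {
        std::size_t cix = ix + (std::size_t)grid.nx * iy;
        int hint = ingrid ? nearseg[cix] : -1;
        int rad = ingrid ? winrad[cix] : 0;
        wall_record(arms[i], s.x[i], s.y[i], env, p, ctx.wall[i], hint, rad);
      }
    }
  } else {
    for (int i = 0; i < n; ++i) {
      ctx.wall[i].contact = false; ctx.wall[i].fx = 0; ctx.wall[i].fy = 0;
    }
  }
  // activity, cached once per step
  ctx.G.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double A, gx, gy;
    sample_stimulus(grid, p, s.x[i], s.y[i], A, gx, gy);
    ctx.G[i] = sat(p.alpha * A - p.beta * ctx.N[i]);
  }
}

// head clamp: shorten l so the head arm stops at the first wall crossing
static void clamp_head(SoA& s, const Env& env, const Grid& grid,
                       const std::vector<double>& clr, const Pars& p) {
  if (!env.has_walls) return;
  for (int i = 0; i < s.n; ++i) {
    double cl = clearance_at(grid, clr, s.x[i], s.y[i]);
    if (cl > s.l[i]) continue;
    double ct = std::cos(s.th[i]), st = std::sin(s.th[i]);
    double hx = s.x[i] + s.l[i] * ct, hy = s.y[i] + s.l[i] * st;
    double rminx = std::min(s.x[i], hx), rmaxx = std::max(s.x[i], hx);
    double rminy = std::min(s.y[i], hy), rmaxy = std::max(s.y[i], hy);
    double tmin = 1e30;
    for (int w = 0; w < env.nw; ++w) {
      if (rminx > env.wmaxx[w] || env.wminx[w] > rmaxx ||
          rminy > env.wmaxy[w] || env.wminy[w] > rmaxy)
        continue;
      double t = ray_seg_hit(s.x[i], s.y[i], ct, st,
                             env.wx1[w], env.wy1[w], env.wx2[w], env.wy2[w]);
      if (t >= 0.0 && t < tmin) tmin = t;
    }
    if (tmin < s.l[i])
      s.l[i] = std::max(p.a, tmin);
  }
}

// --------------------------------------------------------------- stepper ---

struct StepWork {
  std::vector<Arms> arms;
  Cand cd;
  Ctx ctx;
  std::vector<double> f1x, f1y, f2x, f2y, W1, W2;
  std::vector<double> xs, ys, vxs, vys, ths; // predictor stage state
  std::vector<double> Ei, Cv, Cf1, Cfd, ph2, bC;
};

// advance the state by one step of length p.dt, starting at absolute time
// t. The caller owns the verlet clock: the return value is the max
// single-agent motion (displacement + head elongation change).
static double one_step(SoA& s, StepWork& w, const Env& env, Grid& grid,
                       const std::vector<double>& clr,
                       const std::vector<int>& nearseg,
                       const std::vector<int>& winrad, const Pars& p,
                       double t) {
  int n = s.n;
  // random-torque schedule, refreshed once per step in agent order
  for (int i = 0; i < n; ++i) {
    if (t >= s.tref[i]) {
      s.zeta[i] = R::runif(-1.0, 1.0);
      s.tref[i] = t + R::runif(p.t_min, p.t_max);
    }
  }
  refresh_arms(s, p, w.arms);
  ensure_candidates(s, p, w.cd);
  build_ctx(s, w.arms, w.cd, env, grid, clr, nearseg, winrad, p, w.ctx);
  // field update (explicit Euler + deposits at current positions)
  field_step(grid, s.x, s.y, p);
  // stage 1 at the step-start state
  assemble(s.x, s.y, s.vx, s.vy, s.th, s.l, s.zeta, w.ctx, env, grid, p,
           w.f1x, w.f1y, w.W1, 0);
  w.xs.resize(n); w.ys.resize(n); w.vxs.resize(n); w.vys.resize(n);
  w.ths.resize(n);
  w.Ei.resize(n); w.Cv.resize(n); w.Cf1.resize(n); w.Cfd.resize(n);
  w.ph2.resize(n); w.bC.resize(n);
  for (int i = 0; i < n; ++i) {
    // per-agent linear drag handled exactly: ground + pair + peg friction
    double b = p.c + p.q1 * w.ctx.N[i] + p.q2 * (double)w.ctx.pegs[i].size();
    double g = b / p.m, z = g * p.dt;
    double E = std::exp(-z);
    double cv = -std::expm1(-z) / g;          // (1 - E)/gamma = dt*phi1
    double cf1 = (p.dt - cv) / g;
    double cfd, p2;
    if (z > 1e-3) {
      cfd = p.dt * p.dt / (2.0 * g) - p.dt / (g * g) + (1.0 - E) / (g * g * g);
      p2 = (z - 1.0 + E) / (g * g * p.dt);    // dt*phi2
    } else {
      double d3 = p.dt * p.dt * p.dt;
      cfd = d3 * (1.0 / 6.0 - z / 24.0 + z * z / 120.0);
      p2 = p.dt * (0.5 - z / 6.0 + z * z / 24.0);
    }
    w.Ei[i] = E; w.Cv[i] = cv; w.Cf1[i] = cf1; w.Cfd[i] = cfd;
    w.ph2[i] = p2; w.bC[i] = b;
    // explicit part: restore the self-drag that sits inside pair/peg terms
    double addb = b - p.c;
    double fe1x = w.f1x[i] + addb * s.vx[i];
    double fe1y = w.f1y[i] + addb * s.vy[i];
    w.vxs[i] = E * s.vx[i] + cv * fe1x / p.m;
    w.vys[i] = E * s.vy[i] + cv * fe1y / p.m;
    w.xs[i] = s.x[i] + cv * s.vx[i] + cf1 * fe1x / p.m;
    w.ys[i] = s.y[i] + cv * s.vy[i] + cf1 * fe1y / p.m;
    w.ths[i] = s.th[i] + p.dt * w.W1[i];
    w.f1x[i] = fe1x; w.f1y[i] = fe1y;   // f1 now holds the explicit part
  }
  // stage 2 at the predictor state (contacts, field, G frozen)
  assemble(w.xs, w.ys, w.vxs, w.vys, w.ths, s.l, s.zeta, w.ctx, env, grid, p,
           w.f2x, w.f2y, w.W2, 0);
  double maxmove = 0.0;
  for (int i = 0; i < n; ++i) {
    double addb = w.bC[i] - p.c;
    double fe2x = w.f2x[i] + addb * w.vxs[i];
    double fe2y = w.f2y[i] + addb * w.vys[i];
    double E = w.Ei[i];
    double nvx = E * s.vx[i] + w.Cv[i] * w.f1x[i] / p.m +
                 w.ph2[i] * (fe2x - w.f1x[i]) / p.m;
    double nvy = E * s.vy[i] + w.Cv[i] * w.f1y[i] / p.m +
                 w.ph2[i] * (fe2y - w.f1y[i]) / p.m;
    double nx = s.x[i] + w.Cv[i] * s.vx[i] + w.Cf1[i] * w.f1x[i] / p.m +
                w.Cfd[i] * (fe2x - w.f1x[i]) / (p.dt * p.m);
    double ny = s.y[i] + w.Cv[i] * s.vy[i] + w.Cf1[i] * w.f1y[i] / p.m +
                w.Cfd[i] * (fe2y - w.f1y[i]) / (p.dt * p.m);
    double dx = nx - s.x[i], dy = ny - s.y[i];
    double mv = std::sqrt(dx * dx + dy * dy);
    s.x[i] = nx; s.y[i] = ny; s.vx[i] = nvx; s.vy[i] = nvy;
    s.th[i] = wrap_pi(s.th[i] + 0.5 * p.dt * (w.W1[i] + w.W2[i]));
    // head-arm length: Euler relaxation toward the contact-dependent target
    double lbar = std::max(p.l_a - p.l_b * w.ctx.N[i], p.a);
    double lold = s.l[i];
    s.l[i] = s.l[i] + p.dt * (lbar - s.l[i]) / p.tau;
    if (s.l[i] < p.a) s.l[i] = p.a;
    if (s.l[i] > p.l_a) s.l[i] = p.l_a;
    mv += std::fabs(s.l[i] - lold);
    if (mv > maxmove) maxmove = mv;
  }
  clamp_head(s, env, grid, clr, p);
  return maxmove;
}

// ------------------------------------------------------------ R entry pts ---

// [[Rcpp::export]]
List cpp_run(NumericMatrix agents, List params, List env_, List field_,
             int n_steps, int record_stride, double t0, int step0) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (record_stride < 1) stop("record_stride must be >= 1");
  Pars p = parse_pars(params);
  Env env = parse_env(env_);
  Grid grid = parse_grid(field_);
  SoA s = parse_agents(agents);
  std::vector<double> clr;
  std::vector<int> nearseg, winrad;
  clearance_grid(grid, env, clr, nearseg, winrad);
  StepWork w;
  // recorded steps: 0, stride, 2*stride, ..., plus the final step
  std::vector<int> recsteps;
  for (int k = 0; k < n_steps; k += record_stride) recsteps.push_back(k);
  recsteps.push_back(n_steps);
  NumericMatrix frames((std::size_t)recsteps.size() * s.n, 8);
  colnames(frames) = CharacterVector::create("step", "id", "x", "y", "theta",
                                             "l", "G", "N");
  std::size_t row = 0, rec = 0;
  for (int step = 0; step < n_steps; ++step) {
    double t = t0 + (double)step * p.dt;
    if (rec < recsteps.size() && recsteps[rec] == step) {
      // record the pre-step state with that step's fresh contact info
      refresh_arms(s, p, w.arms);
      ensure_candidates(s, p, w.cd);
      build_ctx(s, w.arms, w.cd, env, grid, clr, nearseg, winrad, p, w.ctx);
      for (int i = 0; i < s.n; ++i) {
        frames(row, 0) = step0 + step; frames(row, 1) = i + 1;
        frames(row, 2) = s.x[i]; frames(row, 3) = s.y[i];
        frames(row, 4) = s.th[i]; frames(row, 5) = s.l[i];
        frames(row, 6) = w.ctx.G[i]; frames(row, 7) = w.ctx.N[i];
        ++row;
      }
      ++rec;
    }
    double mv = one_step(s, w, env, grid, clr, nearseg, winrad, p, t);
    w.cd.S += mv;
    if ((step & 255) == 0) {
      for (int i = 0; i < s.n; ++i)
        if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
            !std::isfinite(s.vx[i]) || !std::isfinite(s.th[i]))
          stop("non-finite state at step %d, agent %d", step0 + step, i + 1);
    }
  }
  // final frame
  refresh_arms(s, p, w.arms);
  ensure_candidates(s, p, w.cd);
  build_ctx(s, w.arms, w.cd, env, grid, clr, nearseg, winrad, p, w.ctx);
  for (int i = 0; i < s.n; ++i) {
    frames(row, 0) = step0 + n_steps; frames(row, 1) = i + 1;
    frames(row, 2) = s.x[i]; frames(row, 3) = s.y[i];
    frames(row, 4) = s.th[i]; frames(row, 5) = s.l[i];
    frames(row, 6) = w.ctx.G[i]; frames(row, 7) = w.ctx.N[i];
    ++row;
  }
  for (int i = 0; i < s.n; ++i)
    if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]))
      stop("non-finite state at final step, agent %d", i + 1);
  return List::create(_["frames"] = frames,
                      _["agents"] = agents_matrix(s),
                      _["field_a"] = grid_matrix(grid),
                      _["recorded_steps"] = wrap(recsteps));
}

// contact graph of one frame: i/j are 1-based edge endpoints, N the counts
// [[Rcpp::export]]
List cpp_contact_graph(NumericMatrix agents, double d_contact) {
  int n = agents.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = agents(i, 0); y[i] = agents(i, 1); }
  std::vector<int> ci, cj;
  find_pairs(x, y, d_contact, ci, cj);
  IntegerVector N(n);
  std::vector<int> ei, ej;
  for (std::size_t k = 0; k < ci.size(); ++k) {
    ei.push_back(ci[k] + 1); ej.push_back(cj[k] + 1);
    N[ci[k]]++; N[cj[k]]++;
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej), _["N"] = N);
}

// per-agent lists (1-based) of contacted pegs
// [[Rcpp::export]]
List cpp_peg_contacts(NumericMatrix agents, NumericMatrix pegs, double peg_r,
                      double a_len, double d_contact) {
  int n = agents.nrow(), np = pegs.nrow();
  double thr = peg_r + d_contact, t2 = thr * thr;
  List out(n);
  for (int i = 0; i < n; ++i) {
    Arms A;
    make_arms(agents(i, 0), agents(i, 1), agents(i, 4), agents(i, 5), a_len, A);
    std::vector<int> hit;
    for (int q = 0; q < np; ++q) {
      double dmin2 = 1e30;
      for (int k = 0; k < 4; ++k) {
        double d2 = pt_seg_dist2(pegs(q, 0), pegs(q, 1), A.cx, A.cy,
                                 A.ex[k], A.ey[k]);
        if (d2 < dmin2) dmin2 = d2;
      }
      if (dmin2 <= t2) hit.push_back(q + 1);
    }
    out[i] = wrap(hit);
  }
  return out;
}

// one field update step (exported so the R-level field API shares the
// production kernel)
// [[Rcpp::export]]
NumericMatrix cpp_field_step(NumericMatrix a, LogicalMatrix mask,
                             NumericMatrix agents_xy,
                             double x0, double y0, double dx,
                             double k_A0, double k_A1, double D_A, double dt) {
  Grid g; g.nx = a.nrow(); g.ny = a.ncol(); g.x0 = x0; g.y0 = y0; g.dx = dx;
  g.mustard = false;
  g.a.assign(a.begin(), a.end());
  g.mask.resize(g.a.size());
  for (std::size_t k = 0; k < g.a.size(); ++k) g.mask[k] = mask[k] ? 1 : 0;
  find_ghosts(g);
  Pars p; p.kA0 = k_A0; p.kA1 = k_A1; p.DA = D_A; p.dt = dt;
  std::vector<double> ax(agents_xy.nrow()), ay(agents_xy.nrow());
  for (int i = 0; i < agents_xy.nrow(); ++i) {
    ax[i] = agents_xy(i, 0); ay[i] = agents_xy(i, 1);
  }
  field_step(g, ax, ay, p);
  return grid_matrix(g);
}

// bilinear a_s sample + interpolated central-difference gradient.
// Returns ok = FALSE rows for out-of-grid points (values zeroed).
// [[Rcpp::export]]
List cpp_sample_as(NumericMatrix a, double x0, double y0, double dx,
                   NumericMatrix pts) {
  Grid g; g.nx = a.nrow(); g.ny = a.ncol(); g.x0 = x0; g.y0 = y0; g.dx = dx;
  g.mustard = false;
  g.a.assign(a.begin(), a.end());
  g.mask.assign(g.a.size(), 1);
  int n = pts.nrow();
  NumericVector A(n), gx(n), gy(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    double aa, ggx, ggy;
    ok[i] = sample_as(g, pts(i, 0), pts(i, 1), aa, ggx, ggy);
    A[i] = aa; gx[i] = ggx; gy[i] = ggy;
  }
  return List::create(_["a_s"] = A, _["gx"] = gx, _["gy"] = gy, _["ok"] = ok);
}

// full per-term force/torque breakdown at a given state (the engine's
// production assembly, exposed for diagnostics and for the term-level
// equivalence tests)
// [[Rcpp::export]]
List cpp_force_breakdown(NumericMatrix agents, List params, List env_,
                         List field_) {
  Pars p = parse_pars(params);
  Env env = parse_env(env_);
  Grid grid = parse_grid(field_);
  SoA s = parse_agents(agents);
  std::vector<double> clr;
  std::vector<int> nearseg, winrad;
  clearance_grid(grid, env, clr, nearseg, winrad);
  std::vector<Arms> arms;
  refresh_arms(s, p, arms);
  Cand cd;
  find_pairs(s.x, s.y, p.d_contact, cd.ci, cd.cj);
  cd.valid = true;
  Ctx ctx;
  build_ctx(s, arms, cd, env, grid, clr, nearseg, winrad, p, ctx);
  std::vector<double> fx, fy, W;
  Breakdown bk;
  bk.init(s.n);
  assemble(s.x, s.y, s.vx, s.vy, s.th, s.l, s.zeta, ctx, env, grid, p,
           fx, fy, W, &bk);
  NumericVector A(s.n), gx(s.n), gy(s.n), G(s.n), lbar(s.n);
  IntegerVector N(s.n), npeg(s.n);
  for (int i = 0; i < s.n; ++i) {
    double aa, ggx, ggy;
    sample_stimulus(grid, p, s.x[i], s.y[i], aa, ggx, ggy);
    A[i] = aa; gx[i] = ggx; gy[i] = ggy;
    G[i] = ctx.G[i]; N[i] = ctx.N[i]; npeg[i] = (int)ctx.pegs[i].size();
    lbar[i] = std::max(p.l_a - p.l_b * ctx.N[i], p.a);
  }
  return List::create(
    _["fx"] = wrap(fx), _["fy"] = wrap(fy), _["W"] = wrap(W),
    _["prop_x"] = wrap(bk.propx), _["prop_y"] = wrap(bk.propy),
    _["pair_x"] = wrap(bk.pairx), _["pair_y"] = wrap(bk.pairy),
    _["peg_x"] = wrap(bk.pegx), _["peg_y"] = wrap(bk.pegy),
    _["wall_x"] = wrap(bk.wallx), _["wall_y"] = wrap(bk.wally),
    _["w_rand"] = wrap(bk.wrand), _["w_chem"] = wrap(bk.wchem),
    _["w_nematic"] = wrap(bk.wnem), _["w_peg"] = wrap(bk.wpeg),
    _["w_wall"] = wrap(bk.wwall),
    _["A"] = A, _["grad_x"] = gx, _["grad_y"] = gy,
    _["G"] = G, _["N"] = N, _["n_pegs"] = npeg, _["target_l"] = lbar);
}
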