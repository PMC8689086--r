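// Depth-averaged interpolated thick/thin-limit ("Stokes-Brinkman") flow
// solver on a rasterised obstacle mask.
//
// Governing equations (vertically averaged velocity vbar, in-plane pressure):
//   grad p = mu * lap(vbar) - (12 mu / h^2) * vbar      (momentum)
//   div vbar = 0                                        (continuity)
// discretised on a staggered (MAC) grid: pressures at pixel centres,
// velocity components on pixel faces. Everything here is in lattice units:
// lengths in pixels, velocities in units of the inlet speed v0, pressure in
// units of mu*v0/dx. The drag coefficient is then c = 12*(dx/h)^2.
//
// Boundary conditions: no slip on obstacle and side-wall boundaries
// (staircase walls live on pixel faces; tangential ghosts reflect), uniform
// normal speed (v = 1) with zero tangential velocity on the open inlet
// pixels of the top edge, zero gauge pressure with zero normal-gradient
// outflow on the bottom edge.
//
// Solved with geometric multigrid: damped cell-wise Vanka (symmetric
// coupled Gauss-Seidel) smoothing, rediscretised coarse operators on
// any-child-fluid coarsened masks, V-cycles to a residual tolerance.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

struct Level {
  int nx, ny;
  double c;     // Brinkman drag in this level's lattice units
  double vin;   // inlet Dirichlet speed (finest level only, else 0)
  std::vector<uint8_t> fluid;          // ny*nx
  std::vector<double> u, v, p;         // solution / correction
  std::vector<double> fu, fv, fc;      // right-hand sides
  std::vector<double> ru, rv, rc;      // residual scratch
  std::vector<double> du, dv;          // cached operator diagonals
  inline size_t ci(int i, int j) const { return (size_t)j + (size_t)ny * i; }
  inline size_t ui(int i, int j) const { return (size_t)j + (size_t)ny * i; }
  inline size_t vi(int i, int j) const { return (size_t)j + (size_t)(ny + 1) * i; }
  inline bool fl(int i, int j) const { return fluid[ci(i, j)] != 0; }
  inline bool udof(int i, int j) const {
    return i >= 1 && i <= nx - 1 && fl(i - 1, j) && fl(i, j);
  }
  // v-face types: 0 fixed, 1 interior dof, 2 outlet dof
  inline int vtype(int i, int j) const {
    if (j == 0) return 0;                       // inlet Dirichlet (or solid)
    if (j == ny) return fl(i, ny - 1) ? 2 : 0;  // outlet
    return (fl(i, j - 1) && fl(i, j)) ? 1 : 0;
  }
};

// tangential neighbour of a u-face in y; ghosts: inlet reflect, outlet
// zero-gradient, wall (both adjacent cells solid) reflect
static inline double u_nb_y(const Level& L, int i, int jn, double ucur) {
  if (jn < 0) return -ucur;
  if (jn >= L.ny) return ucur;
  if (!L.fl(i - 1, jn) && !L.fl(i, jn)) return -ucur;
  return L.u[L.ui(i, jn)];
}

// tangential neighbour of a v-face in x; ghosts: side wall / obstacle reflect
static inline double v_nb_x(const Level& L, int in, int j, double vcur) {
  if (in < 0 || in >= L.nx) return -vcur;
  bool wall;
  if (j == 0) wall = !L.fl(in, 0);
  else if (j == L.ny) wall = !L.fl(in, L.ny - 1);
  else wall = !L.fl(in, j - 1) && !L.fl(in, j);
  if (wall) return -vcur;
  return L.v[L.vi(in, j)];
}

// diagonal (positive) of the u momentum operator at a dof face
static inline double u_diag(const Level& L, int i, int j) {
  double d = 4.0 + L.c;
  if (j - 1 < 0) d += 1.0;
  else if (!L.fl(i - 1, j - 1) && !L.fl(i, j - 1)) d += 1.0;
  if (j + 1 >= L.ny) d -= 1.0;
  else if (!L.fl(i - 1, j + 1) && !L.fl(i, j + 1)) d += 1.0;
  return d;
}

static inline double v_diag(const Level& L, int i, int j) {
  double d = 4.0 + L.c;
  // x neighbours
  for (int s = -1; s <= 1; s += 2) {
    int in = i + s;
    bool wall;
    if (in < 0 || in >= L.nx) wall = true;
    else if (j == L.ny) wall = !L.fl(in, L.ny - 1);
    else wall = !L.fl(in, j - 1) && !L.fl(in, j);
    if (wall) d += 1.0;
  }
  if (j == L.ny) d -= 1.0;  // outflow zero-gradient ghost below
  return d;
}

// residual of the u momentum equation at dof face (i,j)
static inline double u_res(const Level& L, int i, int j) {
  double uc = L.u[L.ui(i, j)];
  double lap = L.u[L.ui(i - 1, j)] + L.u[L.ui(i + 1, j)] +
               u_nb_y(L, i, j - 1, uc) + u_nb_y(L, i, j + 1, uc) - 4.0 * uc;
  double gp = L.p[L.ci(i, j)] - L.p[L.ci(i - 1, j)];
  return L.fu[L.ui(i, j)] - (lap - L.c * uc - gp);
}

// residual of the v momentum equation at dof face (i,j); type 1 or 2
static inline double v_res(const Level& L, int i, int j, int type) {
  double vc = L.v[L.vi(i, j)];
  double lap;
  double gp;
  if (type == 2) {  // outlet face j == ny
    lap = v_nb_x(L, i - 1, j, vc) + v_nb_x(L, i + 1, j, vc) +
          L.v[L.vi(i, L.ny - 1)] + vc - 4.0 * vc;
    gp = -2.0 * L.p[L.ci(i, L.ny - 1)];  // ghost p = -p_in, outlet gauge 0
  } else {
    lap = v_nb_x(L, i - 1, j, vc) + v_nb_x(L, i + 1, j, vc) +
          L.v[L.vi(i, j - 1)] + L.v[L.vi(i, j + 1)] - 4.0 * vc;
    gp = L.p[L.ci(i, j)] - L.p[L.ci(i, j - 1)];
  }
  return L.fv[L.vi(i, j)] - (lap - L.c * vc - gp);
}

static void cache_diagonals(Level& L) {
  L.du.assign(L.u.size(), 0.0);
  L.dv.assign(L.v.size(), 0.0);
  for (int i = 1; i <= L.nx - 1; ++i)
    for (int j = 0; j < L.ny; ++j)
      if (L.udof(i, j)) L.du[L.ui(i, j)] = u_diag(L, i, j);
  for (int i = 0; i < L.nx; ++i)
    for (int j = 1; j <= L.ny; ++j)
      if (L.vtype(i, j)) L.dv[L.vi(i, j)] = v_diag(L, i, j);
}

static inline double c_res(const Level& L, int i, int j) {
  double div = L.u[L.ui(i + 1, j)] - L.u[L.ui(i, j)] +
               L.v[L.vi(i, j + 1)] - L.v[L.vi(i, j)];
  return L.fc[L.ci(i, j)] - div;
}

// one damped Vanka sweep (forward if dir > 0, backward otherwise)
static void vanka_sweep(Level& L, double omega, int dir) {
  int i0 = dir > 0 ? 0 : L.nx - 1, i1 = dir > 0 ? L.nx : -1, di = dir > 0 ? 1 : -1;
  for (int i = i0; i != i1; i += di) {
    int j0 = dir > 0 ? 0 : L.ny - 1, j1 = dir > 0 ? L.ny : -1;
    for (int j = j0; j != j1; j += di) {
      if (!L.fl(i, j)) continue;
      // collect dof faces: w,e,n,s
      double r[4], dg[4], g[4], b[4];
      size_t idx[4];
      bool isu[4];
      int nf = 0;
      if (L.udof(i, j)) {
        idx[nf] = L.ui(i, j); isu[nf] = true;
        r[nf] = u_res(L, i, j); dg[nf] = L.du[idx[nf]];
        g[nf] = -1.0; b[nf] = -1.0; ++nf;
      }
      if (L.udof(i + 1, j)) {
        idx[nf] = L.ui(i + 1, j); isu[nf] = true;
        r[nf] = u_res(L, i + 1, j); dg[nf] = L.du[idx[nf]];
        g[nf] = 1.0; b[nf] = 1.0; ++nf;
      }
      int tn = L.vtype(i, j);
      if (tn == 1) {  // north face (j>0); inlet faces are fixed
        idx[nf] = L.vi(i, j); isu[nf] = false;
        r[nf] = v_res(L, i, j, 1); dg[nf] = L.dv[idx[nf]];
        g[nf] = -1.0; b[nf] = -1.0; ++nf;
      }
      int ts = L.vtype(i, j + 1);
      if (ts == 1 || ts == 2) {
        idx[nf] = L.vi(i, j + 1); isu[nf] = false;
        r[nf] = v_res(L, i, j + 1, ts); dg[nf] = L.dv[idx[nf]];
        g[nf] = (ts == 2) ? 2.0 : 1.0; b[nf] = 1.0; ++nf;
      }
      if (nf == 0) continue;
      // local Jacobian solve: momentum rows have diagonal -d and pressure
      // coefficient g; continuity row has face coefficients b
      double rc = c_res(L, i, j);
      double num = rc, den = 0.0;
      for (int f = 0; f < nf; ++f) {
        num += b[f] * r[f] / dg[f];
        den += b[f] * g[f] / dg[f];
      }
      double dp = num / den;
      L.p[L.ci(i, j)] += omega * dp;
      for (int f = 0; f < nf; ++f) {
        double dvel = (g[f] * dp - r[f]) / dg[f];
        if (isu[f]) L.u[idx[f]] += omega * dvel;
        else L.v[idx[f]] += omega * dvel;
      }
    }
  }
}

static void residuals(Level& L, double* rmax_mom, double* rmax_cont) {
  double rm = 0.0, rcm = 0.0;
  std::fill(L.ru.begin(), L.ru.end(), 0.0);
  std::fill(L.rv.begin(), L.rv.end(), 0.0);
  std::fill(L.rc.begin(), L.rc.end(), 0.0);
  for (int i = 1; i <= L.nx - 1; ++i)
    for (int j = 0; j < L.ny; ++j)
      if (L.udof(i, j)) {
        double r = u_res(L, i, j);
        L.ru[L.ui(i, j)] = r;
        if (std::fabs(r) > rm) rm = std::fabs(r);
      }
  for (int i = 0; i < L.nx; ++i)
    for (int j = 1; j <= L.ny; ++j) {
      int t = L.vtype(i, j);
      if (t) {
        double r = v_res(L, i, j, t);
        L.rv[L.vi(i, j)] = r;
        if (std::fabs(r) > rm) rm = std::fabs(r);
      }
    }
  for (int i = 0; i < L.nx; ++i)
    for (int j = 0; j < L.ny; ++j)
      if (L.fl(i, j)) {
        double r = c_res(L, i, j);
        L.rc[L.ci(i, j)] = r;
        if (std::fabs(r) > rcm) rcm = std::fabs(r);
      }
  if (rmax_mom) *rmax_mom = rm;
  if (rmax_cont) *rmax_cont = rcm;
}

static void build_coarse(const Level& F, Level& C) {
  C.nx = (F.nx + 1) / 2;
  C.ny = (F.ny + 1) / 2;
  C.c = 4.0 * F.c;
  C.vin = 0.0;
  C.fluid.assign((size_t)C.nx * C.ny, 0);
  for (int I = 0; I < C.nx; ++I)
    for (int J = 0; J < C.ny; ++J) {
      bool any = false;
      for (int di = 0; di < 2 && !any; ++di)
        for (int dj = 0; dj < 2 && !any; ++dj) {
          int i = 2 * I + di, j = 2 * J + dj;
          if (i < F.nx && j < F.ny && F.fl(i, j)) any = true;
        }
      C.fluid[C.ci(I, J)] = any ? 1 : 0;
    }
  size_t nu = (size_t)C.ny * (C.nx + 1), nv = (size_t)(C.ny + 1) * C.nx,
         nc = (size_t)C.nx * C.ny;
  C.u.assign(nu, 0.0); C.fu.assign(nu, 0.0); C.ru.assign(nu, 0.0);
  C.v.assign(nv, 0.0); C.fv.assign(nv, 0.0); C.rv.assign(nv, 0.0);
  C.p.assign(nc, 0.0); C.fc.assign(nc, 0.0); C.rc.assign(nc, 0.0);
  cache_diagonals(C);
}

// coarse u correction value at (I,J); 0 outside the dof set (walls)
static inline double cu_at(const Level& C, int I, int J) {
  if (I < 1 || I > C.nx - 1 || J < 0 || J >= C.ny) return 0.0;
  return C.udof(I, J) ? C.u[C.ui(I, J)] : 0.0;
}
static inline double cv_at(const Level& C, int I, int J) {
  if (I < 0 || I >= C.nx || J < 0 || J > C.ny) return 0.0;
  return C.vtype(I, J) ? C.v[C.vi(I, J)] : 0.0;
}
static inline double fru(const Level& F, int i, int j) {
  if (i < 1 || i > F.nx - 1 || j < 0 || j >= F.ny) return 0.0;
  return F.udof(i, j) ? F.ru[F.ui(i, j)] : 0.0;
}
static inline double frv(const Level& F, int i, int j) {
  if (i < 0 || i >= F.nx || j < 0 || j > F.ny) return 0.0;
  return F.vtype(i, j) ? F.rv[F.vi(i, j)] : 0.0;
}

// restrict fine residuals into coarse RHS (full weighting, with the
// lattice-unit rescaling: momentum x4, continuity x2)
static void restrict_res(const Level& F, Level& C) {
  std::fill(C.fu.begin(), C.fu.end(), 0.0);
  std::fill(C.fv.begin(), C.fv.end(), 0.0);
  std::fill(C.fc.begin(), C.fc.end(), 0.0);
  for (int I = 0; I < C.nx; ++I)
    for (int J = 0; J < C.ny; ++J) {
      if (!C.fl(I, J)) continue;
      double s = 0.0;
      for (int di = 0; di < 2; ++di)
        for (int dj = 0; dj < 2; ++dj) {
          int i = 2 * I + di, j = 2 * J + dj;
          if (i < F.nx && j < F.ny && F.fl(i, j)) s += F.rc[F.ci(i, j)];
        }
      C.fc[C.ci(I, J)] = 0.5 * s;  // 2 * mean over 4 children
    }
  // u: 6-point full weighting (coincident line 1/2, neighbour lines 1/4,
  // two rows each); total weight 2, so mean = sum/2 and coarse rhs = 4*mean
  for (int I = 1; I <= C.nx - 1; ++I)
    for (int J = 0; J < C.ny; ++J) {
      if (!C.udof(I, J)) continue;
      int i = 2 * I;
      double s = 0.0;
      for (int dj = 0; dj < 2; ++dj) {
        int j = 2 * J + dj;
        s += 0.5 * fru(F, i, j) +
             0.25 * (fru(F, i - 1, j) + fru(F, i + 1, j));
      }
      C.fu[C.ui(I, J)] = 4.0 * s / 2.0;
    }
  for (int I = 0; I < C.nx; ++I)
    for (int J = 1; J <= C.ny; ++J) {
      if (!C.vtype(I, J)) continue;
      int j = 2 * J;
      double s = 0.0;
      for (int di = 0; di < 2; ++di) {
        int i = 2 * I + di;
        s += 0.5 * frv(F, i, j) +
             0.25 * (frv(F, i, j - 1) + frv(F, i, j + 1));
      }
      C.fv[C.vi(I, J)] = 4.0 * s / 2.0;
    }
}

// add bilinearly prolonged coarse correction to the fine solution
static void prolong_add(const Level& C, Level& F) {
  for (int i = 0; i < F.nx; ++i)
    for (int j = 0; j < F.ny; ++j)
      if (F.fl(i, j)) F.p[F.ci(i, j)] += 0.5 * C.p[C.ci(i / 2, j / 2)];
  // u faces: coarse nodes at fine (x, y) = (2I, 2J + 0.5)
  for (int i = 1; i <= F.nx - 1; ++i)
    for (int j = 0; j < F.ny; ++j) {
      if (!F.udof(i, j)) continue;
      double t = (j - 0.5) / 2.0;
      int J0 = (int)std::floor(t);
      double w = t - J0;
      double e;
      if (i % 2 == 0) {
        int I = i / 2;
        e = (1 - w) * cu_at(C, I, J0) + w * cu_at(C, I, J0 + 1);
      } else {
        int I1 = i / 2, I2 = I1 + 1;
        e = 0.5 * ((1 - w) * (cu_at(C, I1, J0) + cu_at(C, I2, J0)) +
                   w * (cu_at(C, I1, J0 + 1) + cu_at(C, I2, J0 + 1)));
      }
      F.u[F.ui(i, j)] += e;
    }
  // v faces: coarse nodes at fine (x, y) = (2I + 0.5, 2J)
  for (int i = 0; i < F.nx; ++i)
    for (int j = 1; j <= F.ny; ++j) {
      if (!F.vtype(i, j)) continue;
      double t = (i - 0.5) / 2.0;
      int I0 = (int)std::floor(t);
      double w = t - I0;
      double e;
      if (j % 2 == 0) {
        int J = j / 2;
        e = (1 - w) * cv_at(C, I0, J) + w * cv_at(C, I0 + 1, J);
      } else {
        int J1 = j / 2, J2 = J1 + 1;
        e = 0.5 * ((1 - w) * (cv_at(C, I0, J1) + cv_at(C, I0, J2)) +
                   w * (cv_at(C, I0 + 1, J1) + cv_at(C, I0 + 1, J2)));
      }
      F.v[F.vi(i, j)] += e;
    }
}

static void vcycle(std::vector<Level>& levels, size_t l, int nu1, int nu2,
                   double omega, int gamma) {
  Level& L = levels[l];
  if (l == levels.size() - 1) {
    for (int s = 0; s < 60; ++s) {
      vanka_sweep(L, omega, 1);
      vanka_sweep(L, omega, -1);
    }
    return;
  }
  for (int s = 0; s < nu1; ++s) vanka_sweep(L, omega, s % 2 ? -1 : 1);
  residuals(L, nullptr, nullptr);
  restrict_res(L, levels[l + 1]);
  Level& C = levels[l + 1];
  std::fill(C.u.begin(), C.u.end(), 0.0);
  std::fill(C.v.begin(), C.v.end(), 0.0);
  std::fill(C.p.begin(), C.p.end(), 0.0);
  for (int g = 0; g < gamma; ++g)
    vcycle(levels, l + 1, nu1, nu2, omega, gamma);
  prolong_add(C, L);
  for (int s = 0; s < nu2; ++s) vanka_sweep(L, omega, s % 2 ? 1 : -1);
}

// ---- Krylov acceleration -------------------------------------------------
// The V-cycle above is a strong smoother but its rediscretised coarse
// operators degrade near dense staircase obstacles; used alone it can
// stagnate. It is therefore applied as a preconditioner inside BiCGStab on
// the full saddle-point system, which is robust to an imperfect coarse-grid
// correction and needs only a handful of long vectors.

struct Vec3 {
  std::vector<double> u, v, p;
  void init(const Level& L) {
    u.assign(L.u.size(), 0.0);
    v.assign(L.v.size(), 0.0);
    p.assign(L.p.size(), 0.0);
  }
  void fill0() {
    std::fill(u.begin(), u.end(), 0.0);
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(p.begin(), p.end(), 0.0);
  }
};

static double dot3(const Vec3& a, const Vec3& b) {
  double s = 0.0;
  for (size_t k = 0; k < a.u.size(); ++k) s += a.u[k] * b.u[k];
  for (size_t k = 0; k < a.v.size(); ++k) s += a.v[k] * b.v[k];
  for (size_t k = 0; k < a.p.size(); ++k) s += a.p[k] * b.p[k];
  return s;
}

static void axpy3(Vec3& y, double a, const Vec3& x) {
  for (size_t k = 0; k < y.u.size(); ++k) y.u[k] += a * x.u[k];
  for (size_t k = 0; k < y.v.size(); ++k) y.v[k] += a * x.v[k];
  for (size_t k = 0; k < y.p.size(); ++k) y.p[k] += a * x.p[k];
}

// residual of the current L.{u,v,p} state against L.{fu,fv,fc} into out
static void residual_vec(Level& L, Vec3& out, double* rm = nullptr,
                         double* rc = nullptr) {
  residuals(L, rm, rc);
  out.u = L.ru;
  out.v = L.rv;
  out.p = L.rc;
}

// y = A x (homogeneous boundary conditions); uses L as workspace
static void apply_op(Level& L, const Vec3& x, Vec3& y) {
  L.u = x.u; L.v = x.v; L.p = x.p;
  std::fill(L.fu.begin(), L.fu.end(), 0.0);
  std::fill(L.fv.begin(), L.fv.end(), 0.0);
  std::fill(L.fc.begin(), L.fc.end(), 0.0);
  residuals(L, nullptr, nullptr);  // r = 0 - A x
  y.u = L.ru; y.v = L.rv; y.p = L.rc;
  for (size_t k = 0; k < y.u.size(); ++k) y.u[k] = -y.u[k];
  for (size_t k = 0; k < y.v.size(); ++k) y.v[k] = -y.v[k];
  for (size_t k = 0; k < y.p.size(); ++k) y.p[k] = -y.p[k];
}

// z = M^{-1} r: one V-cycle on the hierarchy with rhs r, zero start
static void apply_prec(std::vector<Level>& levels, const Vec3& r, Vec3& z,
                       int nu1, int nu2, double omega) {
  Level& L = levels[0];
  L.fu = r.u; L.fv = r.v; L.fc = r.p;
  std::fill(L.u.begin(), L.u.end(), 0.0);
  std::fill(L.v.begin(), L.v.end(), 0.0);
  std::fill(L.p.begin(), L.p.end(), 0.0);
  vcycle(levels, 0, nu1, nu2, omega, 1);
  z.u = L.u; z.v = L.v; z.p = L.p;
}

static double maxabs3(const Vec3& a, double drag_c, bool& mom_ok,
                      bool& cont_ok, double tol) {
  double rm = 0.0, rc = 0.0;
  for (size_t k = 0; k < a.u.size(); ++k)
    rm = std::max(rm, std::fabs(a.u[k]));
  for (size_t k = 0; k < a.v.size(); ++k)
    rm = std::max(rm, std::fabs(a.v[k]));
  for (size_t k = 0; k < a.p.size(); ++k)
    rc = std::max(rc, std::fabs(a.p[k]));
  mom_ok = rm < tol * (1.0 + drag_c);
  cont_ok = rc < tol;
  return std::max(rm, rc);
}

// [[Rcpp::export(name = ".solve_flow_cpp")]]
List solve_flow_cpp(LogicalMatrix solid, double drag_c, double tol,
                    int max_cycles, int nu_pre, int nu_post, double omega,
                    bool quiet, int max_levels = 25, int gamma = 1,
                    Nullable<NumericMatrix> u_init = R_NilValue,
                    Nullable<NumericMatrix> v_init = R_NilValue,
                    Nullable<NumericMatrix> p_init = R_NilValue) {
  int ny = solid.nrow(), nx = solid.ncol();
  std::vector<Level> levels;
  levels.reserve(32);  // push_back must never invalidate references
  levels.resize(1);
  Level& L0 = levels[0];
  L0.nx = nx; L0.ny = ny; L0.c = drag_c; L0.vin = 1.0;
  L0.fluid.assign((size_t)nx * ny, 0);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      L0.fluid[L0.ci(i, j)] = solid(j, i) ? 0 : 1;
  size_t nu = (size_t)ny * (nx + 1), nv = (size_t)(ny + 1) * nx,
         nc = (size_t)nx * ny;
  L0.u.assign(nu, 0.0); L0.fu.assign(nu, 0.0); L0.ru.assign(nu, 0.0);
  L0.v.assign(nv, 0.0); L0.fv.assign(nv, 0.0); L0.rv.assign(nv, 0.0);
  L0.p.assign(nc, 0.0); L0.fc.assign(nc, 0.0); L0.rc.assign(nc, 0.0);
  cache_diagonals(L0);
  // inlet Dirichlet values and an initial guess on the dofs (either the
  // caller's nested-iteration state or a uniform plug)
  if (u_init.isNotNull() && v_init.isNotNull() && p_init.isNotNull()) {
    NumericMatrix U0(u_init), V0(v_init), P0(p_init);
    for (int i = 1; i <= nx - 1; ++i)
      for (int j = 0; j < ny; ++j)
        if (L0.udof(i, j)) L0.u[L0.ui(i, j)] = U0(j, i);
    for (int i = 0; i < nx; ++i)
      for (int j = 1; j <= ny; ++j)
        if (L0.vtype(i, j)) L0.v[L0.vi(i, j)] = V0(j, i);
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        if (L0.fl(i, j)) L0.p[L0.ci(i, j)] = P0(j, i);
    for (int i = 0; i < nx; ++i)
      if (L0.fl(i, 0)) L0.v[L0.vi(i, 0)] = 1.0;
  } else {
    for (int i = 0; i < nx; ++i) {
      if (L0.fl(i, 0)) L0.v[L0.vi(i, 0)] = 1.0;
      for (int j = 1; j <= ny; ++j)
        if (L0.vtype(i, j)) L0.v[L0.vi(i, j)] = 1.0;
    }
  }
  while (true) {
    const Level& F = levels.back();
    if (F.nx <= 4 || F.ny <= 4 || (int)levels.size() >= max_levels) break;
    levels.push_back(Level());
    build_coarse(levels[levels.size() - 2], levels.back());
  }
  // state (with boundary values) lives outside the workspace hierarchy
  Vec3 X;
  X.u = L0.u; X.v = L0.v; X.p = L0.p;

  // b = residual of the initial state (rhs of the correction equation)
  Vec3 b;
  residual_vec(L0, b);

  Vec3 d, r, rhat, pv, v, s, zhat, ztld, t;
  d.init(L0); v.init(L0); s.init(L0); zhat.init(L0); ztld.init(L0);
  t.init(L0);
  r = b; rhat = b; pv = b; pv.fill0();

  bool mom_ok, cont_ok;
  maxabs3(b, drag_c, mom_ok, cont_ok, tol);
  bool conv = mom_ok && cont_ok;
  double rho_old = 1.0, alpha = 1.0, wom = 1.0;
  int cyc = 0;
  bool fresh = true;  // directions need (re)initialisation
  while (!conv && cyc < max_cycles) {
    ++cyc;
    double rho = dot3(rhat, r);
    if (std::fabs(rho) < 1e-290 || (!fresh && std::fabs(wom) < 1e-290)) {
      // BiCGStab breakdown: restart from the current iterate
      apply_op(L0, d, t);
      r = b; axpy3(r, -1.0, t);
      rhat = r; pv.fill0(); fresh = true;
      rho = dot3(rhat, r);
      if (std::fabs(rho) < 1e-290) break;
    }
    if (fresh) { pv = r; fresh = false; }
    else {
      double beta = (rho / rho_old) * (alpha / wom);
      // p = r + beta (p - wom v)
      for (size_t k = 0; k < pv.u.size(); ++k)
        pv.u[k] = r.u[k] + beta * (pv.u[k] - wom * v.u[k]);
      for (size_t k = 0; k < pv.v.size(); ++k)
        pv.v[k] = r.v[k] + beta * (pv.v[k] - wom * v.v[k]);
      for (size_t k = 0; k < pv.p.size(); ++k)
        pv.p[k] = r.p[k] + beta * (pv.p[k] - wom * v.p[k]);
    }
    rho_old = rho;
    apply_prec(levels, pv, zhat, nu_pre, nu_post, omega);
    apply_op(L0, zhat, v);
    double rv = dot3(rhat, v);
    if (std::fabs(rv) < 1e-290) { fresh = true; continue; }
    alpha = rho / rv;
    s = r; axpy3(s, -alpha, v);
    maxabs3(s, drag_c, mom_ok, cont_ok, tol);
    if (mom_ok && cont_ok) {
      axpy3(d, alpha, zhat);
      r = s;
      conv = true;
      break;
    }
    apply_prec(levels, s, ztld, nu_pre, nu_post, omega);
    apply_op(L0, ztld, t);
    double tt = dot3(t, t);
    if (tt < 1e-290) { fresh = true; continue; }
    wom = dot3(t, s) / tt;
    axpy3(d, alpha, zhat);
    axpy3(d, wom, ztld);
    r = s; axpy3(r, -wom, t);
    maxabs3(r, drag_c, mom_ok, cont_ok, tol);
    conv = mom_ok && cont_ok;
    if (!quiet && (cyc % 5 == 0)) {
      double rm_ = 0, rc_ = 0;
      for (size_t k = 0; k < r.u.size(); ++k)
        rm_ = std::max(rm_, std::fabs(r.u[k]));
      for (size_t k = 0; k < r.p.size(); ++k)
        rc_ = std::max(rc_, std::fabs(r.p[k]));
      Rcpp::Rcout << "iter " << cyc << " mom " << rm_ << " cont " << rc_
                  << std::endl;
    }
    if (cyc % 5 == 0) Rcpp::checkUserInterrupt();
  }
  // final state and true residuals
  axpy3(X, 1.0, d);
  L0.u = X.u; L0.v = X.v; L0.p = X.p;
  std::fill(L0.fu.begin(), L0.fu.end(), 0.0);
  std::fill(L0.fv.begin(), L0.fv.end(), 0.0);
  std::fill(L0.fc.begin(), L0.fc.end(), 0.0);
  double rm = 0.0, rc = 0.0;
  residuals(L0, &rm, &rc);
  conv = rm < tol * (1.0 + drag_c) && rc < tol;
  NumericMatrix U(ny, nx + 1), V(ny + 1, nx), P(ny, nx);
  for (int i = 0; i <= nx; ++i)
    for (int j = 0; j < ny; ++j) U(j, i) = L0.u[L0.ui(i, j)];
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j <= ny; ++j) V(j, i) = L0.v[L0.vi(i, j)];
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      P(j, i) = L0.fl(i, j) ? L0.p[L0.ci(i, j)] : NA_REAL;
  return List::create(_["u_face"] = U, _["v_face"] = V, _["p"] = P,
                      _["cycles"] = cyc, _["res_mom"] = rm,
                      _["res_cont"] = rc, _["converged"] = conv,
                      _["n_levels"] = (int)levels.size());
}
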