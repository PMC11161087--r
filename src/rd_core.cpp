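#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Constant-coefficient tridiagonal solver (Thomas algorithm) with factors
// precomputed once per (n, alpha) pair.  Systems have sub = super = -alpha
// and a caller-supplied diagonal.
struct TriFactor {
  int n;
  double alpha;
  std::vector<double> cp;       // modified super-diagonal
  std::vector<double> inv_den;  // 1 / (diag - sub * cp[i-1])

  TriFactor() : n(0), alpha(0.0) {}

  void factor(const std::vector<double> &diag, double alpha_) {
    n = (int)diag.size();
    alpha = alpha_;
    cp.assign(n, 0.0);
    inv_den.assign(n, 0.0);
    inv_den[0] = 1.0 / diag[0];
    cp[0] = -alpha * inv_den[0];
    for (int i = 1; i < n; ++i) {
      double den = diag[i] + alpha * cp[i - 1];  // sub = -alpha
      inv_den[i] = 1.0 / den;
      if (i < n - 1) cp[i] = -alpha * inv_den[i];
    }
  }

  // solve in place; x used as rhs and solution, stride-1 buffer
  void solve(double *x) const {
    x[0] *= inv_den[0];
    for (int i = 1; i < n; ++i)
      x[i] = (x[i] + alpha * x[i - 1]) * inv_den[i];
    for (int i = n - 2; i >= 0; --i)
      x[i] -= cp[i] * x[i + 1];
  }
};

// Backward-Euler 1D diffusion operators: (I - dt*D*L) x = r.
// Neumann (zero-flux): L has mirrored ghost cells, so the end diagonal
// entries of I - dt*D*L are 1 + alpha instead of 1 + 2*alpha.
//
// Both solvers deflate the right-hand side by a reference constant before
// the sweeps: (I - dt*D*L) maps constants to themselves exactly (zero row
// sums of L, and c - 2c + c is exactly 0 in floating point), so solving
// for the deviation keeps spatially uniform states exact fixed points of
// the scheme.  Without this, per-position rounding in the sweeps seeds
// k != 0 modes at ~1e-16 that a Turing-unstable run amplifies by many
// orders of magnitude.
struct NeumannSolver {
  TriFactor tf;
  void setup(int n, double alpha) {
    std::vector<double> diag(n, 1.0 + 2.0 * alpha);
    diag[0] = 1.0 + alpha;
    diag[n - 1] = 1.0 + alpha;
    tf.factor(diag, alpha);
  }
  void solve(double *x) const {
    double m = x[0];
    for (int i = 0; i < tf.n; ++i) x[i] -= m;
    tf.solve(x);
    for (int i = 0; i < tf.n; ++i) x[i] += m;
  }
};

// Periodic: cyclic tridiagonal via the Sherman-Morrison correction; the
// auxiliary vector z is precomputed so each solve costs one Thomas pass
// plus a rank-one update.
struct PeriodicSolver {
  TriFactor tf;
  std::vector<double> z;
  double gamma, beta;
  int n;
  void setup(int n_, double alpha) {
    n = n_;
    double b = 1.0 + 2.0 * alpha;
    beta = -alpha;                 // corner entries
    gamma = -b;
    std::vector<double> diag(n, b);
    diag[0] = b - gamma;
    diag[n - 1] = b - beta * beta / gamma;
    tf.factor(diag, alpha);
    z.assign(n, 0.0);
    z[0] = gamma;
    z[n - 1] = beta;
    tf.solve(z.data());
  }
  void solve(double *x) const {
    double m = x[0];
    for (int i = 0; i < n; ++i) x[i] -= m;
    tf.solve(x);
    double fact = (x[0] + beta * x[n - 1] / gamma) /
                  (1.0 + z[0] + beta * z[n - 1] / gamma);
    for (int i = 0; i < n; ++i) x[i] -= fact * z[i] - m;
  }
};

// 5-point Laplacian, zero-flux in x (rows), periodic in y (columns).
static void laplacian_into(const double *f, double *out, int nx, int ny,
                           double inv_dx2, double inv_dy2) {
  for (int j = 0; j < ny; ++j) {
    int jm = (j == 0) ? ny - 1 : j - 1;
    int jp = (j == ny - 1) ? 0 : j + 1;
    const double *col = f + (size_t)j * nx;
    const double *colm = f + (size_t)jm * nx;
    const double *colp = f + (size_t)jp * nx;
    double *o = out + (size_t)j * nx;
    for (int i = 0; i < nx; ++i) {
      double c = col[i];
      double xm = (i == 0) ? col[0] : col[i - 1];        // mirror ghost
      double xp = (i == nx - 1) ? col[nx - 1] : col[i + 1];
      o[i] = (xm - 2.0 * c + xp) * inv_dx2 + (colm[i] - 2.0 * c + colp[i]) * inv_dy2;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix laplacian_cpp(NumericMatrix field, double dx, double dy) {
  int nx = field.nrow(), ny = field.ncol();
  if (nx < 3 || ny < 3) stop("grid must have at least 3 cells in each direction");
  NumericMatrix out(nx, ny);
  laplacian_into(field.begin(), out.begin(), nx, ny, 1.0 / (dx * dx), 1.0 / (dy * dy));
  return out;
}

static void check_field(const double *f, int n, double neg_tol, double t,
                        const char *name) {
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(f[i]))
      stop("integration failure: non-finite %s at t = %g (cell %d)", name, t, i + 1);
    if (f[i] < -neg_tol)
      stop("integration failure: %s = %g below -%g at t = %g (cell %d)",
           name, f[i], neg_tol, t, i + 1);
  }
}

// apply (I + alpha*Lx) with mirrored (Neumann) ends, in place via buffer
static void apply_x(const double *src, double *dst, int nx, int ny, double alpha) {
  for (int j = 0; j < ny; ++j) {
    const double *c = src + (size_t)j * nx;
    double *o = dst + (size_t)j * nx;
    for (int i = 0; i < nx; ++i) {
      double xm = (i == 0) ? c[0] : c[i - 1];
      double xp = (i == nx - 1) ? c[nx - 1] : c[i + 1];
      o[i] = c[i] + alpha * (xm - 2.0 * c[i] + xp);
    }
  }
}

// apply (I + alpha*Ly) with periodic wrap
static void apply_y(const double *src, double *dst, int nx, int ny, double alpha) {
  for (int j = 0; j < ny; ++j) {
    int jm = (j == 0) ? ny - 1 : j - 1;
    int jp = (j == ny - 1) ? 0 : j + 1;
    const double *c = src + (size_t)j * nx;
    const double *cm = src + (size_t)jm * nx;
    const double *cp = src + (size_t)jp * nx;
    double *o = dst + (size_t)j * nx;
    for (int i = 0; i < nx; ++i)
      o[i] = c[i] + alpha * (cm[i] - 2.0 * c[i] + cp[i]);
  }
}

// Integrate the masked Schnakenberg pair for nsteps of size dt.
//   scheme = "imex": Peaceman-Rachford alternating-direction semi-implicit
//            step; gated kinetics explicit in two half-steps, each
//            diffusion direction implicit in one half-step and explicit in
//            the other.  Second-order splitting whose stationary states
//            satisfy the discrete balance to O(dt^2).
//   scheme = "euler": fully explicit reference scheme.
// Returns final fields, the max|change|/dt trace sampled every trace_every
// steps (and at the final step), and optional field snapshots.
// [[Rcpp::export]]
List rd_run_cpp(NumericMatrix u0, NumericMatrix v0, NumericMatrix mask,
                double a, double b, double Du, double Dv,
                double dx, double dy, double dt, int nsteps,
                std::string scheme, double neg_tol, double t0,
                int trace_every, int snapshot_every) {
  int nx = u0.nrow(), ny = u0.ncol();
  if (v0.nrow() != nx || v0.ncol() != ny || mask.nrow() != nx || mask.ncol() != ny)
    stop("u, v and mask must share one grid");
  size_t n = (size_t)nx * ny;
  bool imex = (scheme == "imex");
  if (!imex && scheme != "euler") stop("unknown scheme '%s'", scheme.c_str());
  if (trace_every < 1) trace_every = 1;

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> up(n), vp(n), lu, lv;
  const double *S = mask.begin();

  // half-step diffusion numbers alpha = (dt/2) D / h^2
  double aux = 0.5 * dt * Du / (dx * dx), avx = 0.5 * dt * Dv / (dx * dx);
  double auy = 0.5 * dt * Du / (dy * dy), avy = 0.5 * dt * Dv / (dy * dy);
  NeumannSolver nux, nvx;
  PeriodicSolver puy, pvy;
  std::vector<double> buf, w1, w2;
  if (imex) {
    nux.setup(nx, aux);
    nvx.setup(nx, avx);
    puy.setup(ny, auy);
    pvy.setup(ny, avy);
    buf.assign(ny, 0.0);
    w1.assign(n, 0.0);
    w2.assign(n, 0.0);
  } else {
    lu.assign(n, 0.0);
    lv.assign(n, 0.0);
  }

  std::vector<double> trace_t, trace_rate;
  int n_snap = (snapshot_every > 0) ? nsteps / snapshot_every : 0;
  NumericVector snaps_u(n_snap > 0 ? n_snap * n : 0),
      snaps_v(n_snap > 0 ? n_snap * n : 0);
  NumericVector snap_times(n_snap);
  int snap_idx = 0;
  double inv_dx2 = 1.0 / (dx * dx), inv_dy2 = 1.0 / (dy * dy);

  for (int s = 0; s < nsteps; ++s) {
    std::memcpy(up.data(), u.data(), n * sizeof(double));
    std::memcpy(vp.data(), v.data(), n * sizeof(double));

    if (imex) {
      // first half-step: explicit y-diffusion + kinetics, implicit x
      apply_y(u.data(), w1.data(), nx, ny, auy);
      apply_y(v.data(), w2.data(), nx, ny, avy);
      for (size_t i = 0; i < n; ++i) {
        double ui = u[i], vi = v[i], uuv = ui * ui * vi, Si = S[i];
        w1[i] += 0.5 * dt * Si * (a - ui + uuv);
        w2[i] += 0.5 * dt * Si * (b - uuv);
      }
      for (int j = 0; j < ny; ++j) {
        nux.solve(w1.data() + (size_t)j * nx);
        nvx.solve(w2.data() + (size_t)j * nx);
      }
      // second half-step: explicit x-diffusion + kinetics at the
      // intermediate state, implicit y
      apply_x(w1.data(), u.data(), nx, ny, aux);
      apply_x(w2.data(), v.data(), nx, ny, avx);
      for (size_t i = 0; i < n; ++i) {
        double ui = w1[i], vi = w2[i], uuv = ui * ui * vi, Si = S[i];
        u[i] += 0.5 * dt * Si * (a - ui + uuv);
        v[i] += 0.5 * dt * Si * (b - uuv);
      }
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) buf[j] = u[(size_t)j * nx + i];
        puy.solve(buf.data());
        for (int j = 0; j < ny; ++j) u[(size_t)j * nx + i] = buf[j];
        for (int j = 0; j < ny; ++j) buf[j] = v[(size_t)j * nx + i];
        pvy.solve(buf.data());
        for (int j = 0; j < ny; ++j) v[(size_t)j * nx + i] = buf[j];
      }
    } else {
      laplacian_into(u.data(), lu.data(), nx, ny, inv_dx2, inv_dy2);
      laplacian_into(v.data(), lv.data(), nx, ny, inv_dx2, inv_dy2);
      for (size_t i = 0; i < n; ++i) {
        double ui = u[i], vi = v[i], uuv = ui * ui * vi, Si = S[i];
        u[i] = ui + dt * (Du * lu[i] + Si * (a - ui + uuv));
        v[i] = vi + dt * (Dv * lv[i] + Si * (b - uuv));
      }
    }

    double t = t0 + (s + 1) * dt;
    bool at_trace = ((s + 1) % trace_every == 0) || (s == nsteps - 1);
    if (at_trace) {
      check_field(u.data(), (int)n, neg_tol, t, "u");
      check_field(v.data(), (int)n, neg_tol, t, "v");
      double m = 0.0;
      for (size_t i = 0; i < n; ++i) {
        double du = std::fabs(u[i] - up[i]);
        double dv = std::fabs(v[i] - vp[i]);
        if (du > m) m = du;
        if (dv > m) m = dv;
      }
      trace_t.push_back(t);
      trace_rate.push_back(m / dt);
    }
    if (snapshot_every > 0 && (s + 1) % snapshot_every == 0 && snap_idx < n_snap) {
      std::memcpy(&snaps_u[(size_t)snap_idx * n], u.data(), n * sizeof(double));
      std::memcpy(&snaps_v[(size_t)snap_idx * n], v.data(), n * sizeof(double));
      snap_times[snap_idx] = t;
      ++snap_idx;
    }
  }

  NumericMatrix uo(nx, ny), vo(nx, ny);
  std::memcpy(uo.begin(), u.data(), n * sizeof(double));
  std::memcpy(vo.begin(), v.data(), n * sizeof(double));
  List out = List::create(
      _["u"] = uo, _["v"] = vo,
      _["trace_time"] = wrap(trace_t), _["trace_rate"] = wrap(trace_rate));
  if (n_snap > 0) {
    snaps_u.attr("dim") = IntegerVector::create(nx, ny, n_snap);
    snaps_v.attr("dim") = IntegerVector::create(nx, ny, n_snap);
    out["snapshots_u"] = snaps_u;
    out["snapshots_v"] = snaps_v;
    out["snapshot_times"] = snap_times;
  }
  return out;
}

// 4-connected component labelling of a binary matrix, optionally wrapping
// across the periodic column (y) boundary.  Returns 0 for background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool wrap_y) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < ny; ++j0) {
    for (int i0 = 0; i0 < nx; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(i0 + j0 * nx);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int c = stack.back();
        stack.pop_back();
        int ci = c % nx, cj = c / nx;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; ++q) {
          int ni = ci + di[q], nj = cj + dj[q];
          if (ni < 0 || ni >= nx) continue;  // no wrap in x (zero-flux side)
          if (nj < 0 || nj >= ny) {
            if (!wrap_y) continue;
            nj = (nj + ny) % ny;
          }
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nx);
          }
        }
      }
    }
  }
  return lab;
}
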