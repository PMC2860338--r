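// Computational kernels: area-weighted fan-beam projector (polygon clipping),
// full-depth orthonormal 2D Haar transform, lp shrinkage / ball projection,
// and the SART-type projected-gradient iteration loop.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// polygon clipping (Sutherland-Hodgman against a half-plane nx*x+ny*y >= d)

static int clip_half(const double* px, const double* py, int np,
                     double nx, double ny, double d,
                     double* qx, double* qy) {
  int nq = 0;
  for (int i = 0; i < np; ++i) {
    int j = (i + 1) % np;
    double si = nx * px[i] + ny * py[i] - d;
    double sj = nx * px[j] + ny * py[j] - d;
    if (si >= 0) { qx[nq] = px[i]; qy[nq] = py[i]; ++nq; }
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      double t = si / (si - sj);
      qx[nq] = px[i] + t * (px[j] - px[i]);
      qy[nq] = py[i] + t * (py[j] - py[i]);
      ++nq;
    }
  }
  return nq;
}

static double poly_area(const double* px, const double* py, int np) {
  double a = 0.0;
  for (int i = 0; i < np; ++i) {
    int j = (i + 1) % np;
    a += px[i] * py[j] - px[j] * py[i];
  }
  return 0.5 * std::fabs(a);
}

// Exact area of intersection of a convex polygon (tri) with the axis-aligned
// square [x0,x0+s] x [y0,y0+s]; clips the square against the polygon's edges.
static double square_tri_area(double x0, double y0, double s,
                              const double* tx, const double* ty, int nt,
                              double orient) {
  double ax[16], ay[16], bx[16], by[16];
  ax[0] = x0;     ay[0] = y0;
  ax[1] = x0 + s; ay[1] = y0;
  ax[2] = x0 + s; ay[2] = y0 + s;
  ax[3] = x0;     ay[3] = y0 + s;
  int np = 4;
  double* cx = ax; double* cy = ay; double* dx = bx; double* dy = by;
  for (int e = 0; e < nt; ++e) {
    int f = (e + 1) % nt;
    // inward normal of edge e->f for a polygon with signed orientation 'orient'
    double nx = -(ty[f] - ty[e]) * orient;
    double ny =  (tx[f] - tx[e]) * orient;
    double d = nx * tx[e] + ny * ty[e];
    np = clip_half(cx, cy, np, nx, ny, d, dx, dy);
    std::swap(cx, dx); std::swap(cy, dy);
    if (np == 0) return 0.0;
  }
  return poly_area(cx, cy, np);
}

// ---------------------------------------------------------------------------
// fan-beam system matrix
//
// Conventions (shared across the package): image square is
// [-fov/2, fov/2]^2, pixel (r,c) 0-based with r down, c right; pixel index
// j = c*n + r (column-major); source at angle th sits at (-R sin th, R cos th),
// the flat detector passes through the origin along u = (cos th, sin th).

// [[Rcpp::export]]
List cpp_fan_system(double src_radius, double det_length, int n_det,
                    NumericVector angles, int n, double fov, double drop_tol) {
  const int n_views = angles.size();
  const double half = fov / 2.0;
  const double psz = fov / n;
  const double det_w = det_length / n_det;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(1 << 20); tj.reserve(1 << 20); tx.reserve(1 << 20);

  double px[16], py[16], qx[16], qy[16];

  for (int v = 0; v < n_views; ++v) {
    const double th = angles[v];
    const double sx = -src_radius * std::sin(th);
    const double sy =  src_radius * std::cos(th);
    const double ux = std::cos(th), uy = std::sin(th);
    for (int d = 0; d < n_det; ++d) {
      const double t0 = -det_length / 2.0 + d * det_w;
      const double t1 = t0 + det_w;
      double e0x = t0 * ux, e0y = t0 * uy;
      double e1x = t1 * ux, e1y = t1 * uy;
      // extend the element endpoints away from the source so the beam
      // triangle covers the far side of the image square
      const double need = src_radius + 0.7072 * fov;
      double v0x = e0x - sx, v0y = e0y - sy;
      double v1x = e1x - sx, v1y = e1y - sy;
      double l0 = std::sqrt(v0x * v0x + v0y * v0y);
      double l1 = std::sqrt(v1x * v1x + v1y * v1y);
      double f0 = 1.05 * need / l0, f1 = 1.05 * need / l1;
      if (f0 < 1.0) f0 = 1.0;
      if (f1 < 1.0) f1 = 1.0;
      double trix[3] = { sx, sx + f0 * v0x, sx + f1 * v1x };
      double triy[3] = { sy, sy + f0 * v0y, sy + f1 * v1y };
      double sgn = 0.0;
      for (int i = 0; i < 3; ++i) {
        int j = (i + 1) % 3;
        sgn += trix[i] * triy[j] - trix[j] * triy[i];
      }
      const double orient = (sgn >= 0) ? 1.0 : -1.0;

      // clip the triangle to the image square to get a candidate bbox
      for (int i = 0; i < 3; ++i) { px[i] = trix[i]; py[i] = triy[i]; }
      int np = 3;
      np = clip_half(px, py, np,  1.0, 0.0, -half, qx, qy);
      if (np) np = clip_half(qx, qy, np, -1.0, 0.0, -half, px, py);
      if (np) np = clip_half(px, py, np,  0.0, 1.0, -half, qx, qy);
      if (np) np = clip_half(qx, qy, np,  0.0, -1.0, -half, px, py);
      if (np == 0) continue;
      double bx0 = px[0], bx1 = px[0], by0 = py[0], by1 = py[0];
      for (int i = 1; i < np; ++i) {
        bx0 = std::min(bx0, px[i]); bx1 = std::max(bx1, px[i]);
        by0 = std::min(by0, py[i]); by1 = std::max(by1, py[i]);
      }
      int c0 = std::max(0, (int)std::floor((bx0 + half) / psz));
      int c1 = std::min(n - 1, (int)std::floor((bx1 + half) / psz + 1e-12));
      int r0 = std::max(0, (int)std::floor((half - by1) / psz));
      int r1 = std::min(n - 1, (int)std::floor((half - by0) / psz + 1e-12));
      const int m = v * n_det + d;

      for (int r = r0; r <= r1; ++r) {
        const double ylo = half - (r + 1) * psz;
        const double yhi = half - r * psz;
        // x-range of the triangle within this row band, from its edges
        double xmin = 1e300, xmax = -1e300;
        bool any = false;
        for (int i = 0; i < 3; ++i) {
          int j = (i + 1) % 3;
          double yi = triy[i], yj = triy[j];
          double xi = trix[i], xj = trix[j];
          if (yi >= ylo && yi <= yhi) {
            xmin = std::min(xmin, xi); xmax = std::max(xmax, xi); any = true;
          }
          double dy = yj - yi;
          if (std::fabs(dy) > 1e-300) {
            for (int b = 0; b < 2; ++b) {
              double yb = b ? yhi : ylo;
              double t = (yb - yi) / dy;
              if (t >= 0.0 && t <= 1.0) {
                double xb = xi + t * (xj - xi);
                xmin = std::min(xmin, xb); xmax = std::max(xmax, xb); any = true;
              }
            }
          }
        }
        if (!any) continue;
        int cc0 = std::max(c0, (int)std::floor((xmin + half) / psz) - 1);
        int cc1 = std::min(c1, (int)std::floor((xmax + half) / psz) + 1);
        for (int c = cc0; c <= cc1; ++c) {
          const double x0 = -half + c * psz;
          const double y0 = ylo;
          double a = square_tri_area(x0, y0, psz, trix, triy, 3, orient);
          if (a > drop_tol) {
            ti.push_back(m + 1);
            tj.push_back(c * n + r + 1);
            tx.push_back(a);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx),
                      _["M"] = n_views * n_det, _["N"] = n * n);
}

// ---------------------------------------------------------------------------
// orthonormal 2D Haar, full dyadic depth, column-major n x n buffers

static void haar_step(double* x, int s, int stride, double* tmp) {
  const int h = s / 2;
  for (int i = 0; i < h; ++i) {
    double a = x[(2 * i) * stride], b = x[(2 * i + 1) * stride];
    tmp[i]     = (a + b) * M_SQRT1_2;
    tmp[h + i] = (a - b) * M_SQRT1_2;
  }
  for (int i = 0; i < s; ++i) x[i * stride] = tmp[i];
}

static void haar_unstep(double* x, int s, int stride, double* tmp) {
  const int h = s / 2;
  for (int i = 0; i < h; ++i) {
    double a = x[i * stride], d = x[(h + i) * stride];
    tmp[2 * i]     = (a + d) * M_SQRT1_2;
    tmp[2 * i + 1] = (a - d) * M_SQRT1_2;
  }
  for (int i = 0; i < s; ++i) x[i * stride] = tmp[i];
}

static void haar2_forward(double* x, int n, double* tmp) {
  for (int s = n; s >= 2; s /= 2) {
    for (int r = 0; r < s; ++r) haar_step(x + r, s, n, tmp);
    for (int c = 0; c < s; ++c) haar_step(x + c * n, s, 1, tmp);
  }
}

static void haar2_inverse(double* x, int n, double* tmp) {
  for (int s = 2; s <= n; s *= 2) {
    for (int c = 0; c < s; ++c) haar_unstep(x + c * n, s, 1, tmp);
    for (int r = 0; r < s; ++r) haar_unstep(x + r, s, n, tmp);
  }
}

// [[Rcpp::export]]
NumericVector cpp_haar2_forward(NumericVector f, int n) {
  NumericVector out = clone(f);
  std::vector<double> tmp(n);
  haar2_forward(out.begin(), n, tmp.data());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_haar2_inverse(NumericVector c, int n) {
  NumericVector out = clone(c);
  std::vector<double> tmp(n);
  haar2_inverse(out.begin(), n, tmp.data());
  return out;
}

// ---------------------------------------------------------------------------
// shrinkage S_{w,p} = F_{w,p}^{-1}, F_{w,p}(x) = x + w p sgn(x)|x|^{p-1}

static double shrink_scalar(double y, double p, double w) {
  if (w == 0.0 || y == 0.0) return y;
  if (p == 1.0) {
    if (y >= w) return y - w;
    if (y <= -w) return y + w;
    return 0.0;
  }
  if (p == 2.0) return y / (1.0 + 2.0 * w);
  const double s = (y < 0) ? -1.0 : 1.0;
  const double ay = std::fabs(y);
  if (p == 1.5) {
    double D = std::sqrt(9.0 * w * w + 16.0 * ay);
    return s * (ay - 3.0 * w * (D - 3.0 * w) / 8.0);
  }
  // general p in (1,2): invert t + w p t^(p-1) = ay on [0, ay],
  // safeguarded Newton (the map is increasing and concave there)
  double lo = 0.0, hi = ay, t = ay;
  const double tol = 1e-12 * std::max(1.0, ay);
  for (int it = 0; it < 200; ++it) {
    double g = t + w * p * std::pow(t, p - 1.0) - ay;
    if (std::fabs(g) <= tol) break;
    if (g > 0) hi = t; else lo = t;
    double dg = 1.0 + w * p * (p - 1.0) * std::pow(t, p - 2.0);
    double tn = (R_finite(dg) && dg > 0) ? t - g / dg : 0.5 * (lo + hi);
    if (!(tn > lo && tn < hi)) tn = 0.5 * (lo + hi);
    t = tn;
  }
  return s * t;
}

// [[Rcpp::export]]
NumericVector cpp_shrink(NumericVector y, double p, double w) {
  int N = y.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = shrink_scalar(y[i], p, w);
  return out;
}

static double lp_rad(const double* c, int N, double p) {
  double s = 0.0;
  if (p == 1.0) {
    for (int i = 0; i < N; ++i) s += std::fabs(c[i]);
    return s;
  }
  if (p == 2.0) {
    for (int i = 0; i < N; ++i) s += c[i] * c[i];
    return std::sqrt(s);
  }
  for (int i = 0; i < N; ++i) s += std::pow(std::fabs(c[i]), p);
  return std::pow(s, 1.0 / p);
}

static double shrunk_radius(const double* c, int N, double p, double mu) {
  if (p == 1.0) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      double a = std::fabs(c[i]) - mu;
      if (a > 0) s += a;
    }
    return s;
  }
  double s = 0.0;
  if (p == 2.0) {
    double sc = 1.0 / (1.0 + 2.0 * mu);
    for (int i = 0; i < N; ++i) s += c[i] * c[i] * sc * sc;
    return std::sqrt(s);
  }
  for (int i = 0; i < N; ++i)
    s += std::pow(std::fabs(shrink_scalar(c[i], p, mu)), p);
  return std::pow(s, 1.0 / p);
}

// projection onto the lp ball of radius R by dichotomy on the threshold mu;
// modifies c in place, returns mu
static double project_ball(double* c, int N, double R, double p,
                           double tol_rel, int max_steps) {
  double r0 = lp_rad(c, N, p);
  if (r0 <= R) return 0.0;
  double cmax = 0.0;
  for (int i = 0; i < N; ++i) cmax = std::max(cmax, std::fabs(c[i]));
  if (R <= 0.0) {
    for (int i = 0; i < N; ++i) c[i] = 0.0;
    return cmax;
  }
  double lo = 0.0, hi = cmax;
  int guard = 0;
  while (shrunk_radius(c, N, p, hi) > R && guard++ < 60) hi *= 2.0;
  const double tol = tol_rel * std::max(1.0, R);
  double mu = 0.5 * (lo + hi);
  for (int it = 0; it < max_steps; ++it) {
    mu = 0.5 * (lo + hi);
    double r = shrunk_radius(c, N, p, mu);
    if (std::fabs(r - R) <= tol) break;
    if (r > R) lo = mu; else hi = mu;
  }
  for (int i = 0; i < N; ++i) c[i] = shrink_scalar(c[i], p, mu);
  return mu;
}

// [[Rcpp::export]]
List cpp_project_ball(NumericVector c, double R, double p,
                      double tol_rel, int max_steps) {
  NumericVector out = clone(c);
  double mu = project_ball(out.begin(), out.size(), R, p, tol_rel, max_steps);
  return List::create(_["coeffs"] = out, _["mu"] = mu);
}

// ---------------------------------------------------------------------------
// SART-type projected-gradient iteration loop
//
// A is a dgCMatrix (CSC) of size M x N. lam_row holds 1/a_{m+} (0 for beams
// that miss the grid), lam_col holds 1/a_{+n} (0 for pixels never hit); for
// the direct variants both are identically 1 and alpha = 1.
// Per iteration: rt = LamC A' LamR (g - A f); beta = |rt|^2/|A rt|^2;
// f <- f + alpha beta rt, then (schemes with projection) transform to the
// Haar domain, project onto the lp ball of radius R (fixed or the interior
// schedule), transform back.

// [[Rcpp::export]]
List cpp_run_scheme(S4 A, NumericVector g,
                    NumericVector lam_row, NumericVector lam_col,
                    NumericVector f0, NumericVector f_true, bool has_truth,
                    double alpha, bool use_beta, bool project, bool interior,
                    double p, double R_star, int nside,
                    int max_iter, double rre_stop,
                    double mu_tol, int mu_max_steps, double div_factor,
                    double int_base, double int_gain, double int_expo) {
  IntegerVector Ap = A.slot("p");
  IntegerVector Ai = A.slot("i");
  NumericVector Ax = A.slot("x");
  IntegerVector dim = A.slot("Dim");
  const int M = dim[0], N = dim[1];

  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> res(M), rt(N), Ar(M), buf(N), tmp(nside > 0 ? nside : 1);

  double truth_norm = 0.0;
  if (has_truth) {
    for (int i = 0; i < N; ++i) truth_norm += f_true[i] * f_true[i];
    truth_norm = std::sqrt(truth_norm);
  }
  auto rre_of = [&](const std::vector<double>& x) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = x[i] - f_true[i];
      s += d * d;
    }
    return 100.0 * std::sqrt(s) / truth_norm;
  };

  std::vector<double> log_rre, log_beta, log_mu, log_disc;
  log_rre.reserve(max_iter); log_beta.reserve(max_iter);
  log_mu.reserve(max_iter); log_disc.reserve(max_iter);

  double E0 = has_truth ? rre_of(f) : 0.0;
  double disc0 = -1.0;
  int status = 1;  // 1 = max_iter reached
  int k_done = 0;

  for (int k = 1; k <= max_iter; ++k) {
    // res = g - A f
    for (int m = 0; m < M; ++m) res[m] = g[m];
    for (int j = 0; j < N; ++j) {
      double fj = f[j];
      if (fj != 0.0)
        for (int q = Ap[j]; q < Ap[j + 1]; ++q) res[Ai[q]] -= Ax[q] * fj;
    }
    double disc = 0.0;
    for (int m = 0; m < M; ++m) disc += res[m] * res[m];
    disc = std::sqrt(disc);
    if (disc0 < 0) disc0 = disc;

    // rt = LamC A' LamR res
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int q = Ap[j]; q < Ap[j + 1]; ++q) {
        int m = Ai[q];
        s += Ax[q] * lam_row[m] * res[m];
      }
      rt[j] = lam_col[j] * s;
    }

    double beta = 1.0, step;
    if (use_beta) {
      double num = 0.0;
      for (int j = 0; j < N; ++j) num += rt[j] * rt[j];
      for (int m = 0; m < M; ++m) Ar[m] = 0.0;
      for (int j = 0; j < N; ++j) {
        double rj = rt[j];
        if (rj != 0.0)
          for (int q = Ap[j]; q < Ap[j + 1]; ++q) Ar[Ai[q]] += Ax[q] * rj;
      }
      double den = 0.0;
      for (int m = 0; m < M; ++m) den += Ar[m] * Ar[m];
      if (num == 0.0 || den == 0.0) {
        // rt = 0: already consistent; Ar = 0 with rt != 0: stagnation
        status = (num == 0.0) ? 0 : 3;
        log_rre.push_back(has_truth ? rre_of(f) : NA_REAL);
        log_beta.push_back(NA_REAL);
        log_mu.push_back(NA_REAL);
        log_disc.push_back(disc);
        k_done = k;
        break;
      }
      beta = num / den;
      step = alpha * beta;
    } else {
      step = alpha;  // classical SART relaxation lambda
    }
    for (int j = 0; j < N; ++j) f[j] += step * rt[j];

    double mu = 0.0;
    if (project) {
      std::copy(f.begin(), f.end(), buf.begin());
      haar2_forward(buf.data(), nside, tmp.data());
      double Rk = interior
        ? (int_base + int_gain * std::pow((double)k / max_iter, int_expo)) * R_star
        : R_star;
      mu = project_ball(buf.data(), N, Rk, p, mu_tol, mu_max_steps);
      haar2_inverse(buf.data(), nside, tmp.data());
      std::copy(buf.begin(), buf.end(), f.begin());
    }

    double E = has_truth ? rre_of(f) : NA_REAL;
    log_rre.push_back(E);
    log_beta.push_back(use_beta ? beta : NA_REAL);
    log_mu.push_back(project ? mu : NA_REAL);
    log_disc.push_back(disc);
    k_done = k;

    bool bad = false;
    if (has_truth) {
      if (!R_finite(E) || (E0 > 0 && E > div_factor * E0)) bad = true;
    } else if (!R_finite(disc) || (disc0 > 0 && disc > div_factor * disc0)) {
      bad = true;
    }
    if (bad) { status = 2; break; }
    if (has_truth && E < rre_stop) { status = 0; break; }
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["f"] = wrap(f), _["iterations"] = k_done, _["status"] = status,
    _["rre"] = wrap(log_rre), _["beta"] = wrap(log_beta),
    _["mu"] = wrap(log_mu), _["discrepancy"] = wrap(log_disc));
}
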