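#include "nevosim.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// membrane parsing and papilla lookup

static PPoly parse_ppoly(const List& pp) {
  PPoly out;
  NumericVector br = pp["breaks"];
  NumericMatrix cf = pp["coef"];            // 6 x m
  out.breaks.assign(br.begin(), br.end());
  const int m = cf.ncol();
  out.coef.resize(6 * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < 6; ++i) out.coef[6 * j + i] = cf(i, j);
  return out;
}

Membrane parse_membrane(const List& mem) {
  Membrane M;
  NumericVector ext = mem["extent"];
  M.Lx = ext[0]; M.Ly = ext[1];
  List pap = mem["papillae"];
  M.pap.reserve(pap.size());
  for (int i = 0; i < pap.size(); ++i) {
    List p = pap[i];
    Papilla P;
    NumericVector ctr = p["center"];
    P.cx = ctr[0]; P.cy = ctr[1];
    P.R = as<double>(p["R"]); P.H = as<double>(p["H"]);
    P.r = parse_ppoly(p["r_pp"]);
    P.h = parse_ppoly(p["h_pp"]);
    M.pap.push_back(P);
  }
  if (mem.containsElementNamed("deformation")) {
    List def = mem["deformation"];
    for (int i = 0; i < def.size(); ++i) {
      List b = def[i];
      Bump B;
      NumericVector ctr = b["center"];
      B.cx = ctr[0]; B.cy = ctr[1];
      B.rad = as<double>(b["radius"]); B.amp = as<double>(b["amplitude"]);
      M.bumps.push_back(B);
    }
    if (!M.bumps.empty()) M.prof = parse_ppoly(mem["profile_pp"]);
  }
  M.build_grid();
  return M;
}

void Membrane::build_grid() {
  double rmax = 10.0;
  for (const Papilla& P : pap) rmax = std::max(rmax, P.R);
  cell = 2.0 * rmax;
  ngx = std::max(1, (int)std::ceil(Lx / cell));
  ngy = std::max(1, (int)std::ceil(Ly / cell));
  grid.assign((size_t)ngx * ngy, {});
  for (int i = 0; i < (int)pap.size(); ++i) {
    const Papilla& P = pap[i];
    int x0 = std::max(0, (int)std::floor((P.cx - P.R) / cell));
    int x1 = std::min(ngx - 1, (int)std::floor((P.cx + P.R) / cell));
    int y0 = std::max(0, (int)std::floor((P.cy - P.R) / cell));
    int y1 = std::min(ngy - 1, (int)std::floor((P.cy + P.R) / cell));
    for (int gx = x0; gx <= x1; ++gx)
      for (int gy = y0; gy <= y1; ++gy)
        grid[(size_t)gy * ngx + gx].push_back(i);
  }
}

int Membrane::find(double x, double y) const {
  if (pap.empty()) return -1;
  int gx = (int)std::floor(x / cell), gy = (int)std::floor(y / cell);
  if (gx < 0 || gy < 0 || gx >= ngx || gy >= ngy) return -1;
  for (int i : grid[(size_t)gy * ngx + gx]) {
    const Papilla& P = pap[i];
    double dx = x - P.cx, dy = y - P.cy;
    if (dx * dx + dy * dy < P.R * P.R) return i;
  }
  return -1;
}

double Membrane::chi(double x, double y) const {
  double z = 0.0;
  for (const Bump& b : bumps) {
    double dx = x - b.cx, dy = y - b.cy;
    double s = std::sqrt(dx * dx + dy * dy);
    if (s < b.rad) z += b.amp * prof.eval(s / b.rad, 0);
  }
  return z;
}

void Membrane::chi_grad(double x, double y, double& gx, double& gy) const {
  gx = 0.0; gy = 0.0;
  for (const Bump& b : bumps) {
    double dx = x - b.cx, dy = y - b.cy;
    double s = std::sqrt(dx * dx + dy * dy);
    if (s > 1e-12 && s < b.rad) {
      double dp = b.amp * prof.eval(s / b.rad, 1) / b.rad;
      gx += dp * dx / s; gy += dp * dy / s;
    }
  }
}

// ---------------------------------------------------------------------------
// surface embedding, Jacobian, metric

void surf_point(const Membrane& M, double u1, double u2, double out[3]) {
  int j = M.find(u1, u2);
  double px = u1, py = u2, z = 0.0;
  if (j >= 0) {
    const Papilla& P = M.pap[j];
    double wx = u1 - P.cx, wy = u2 - P.cy;
    double th = std::sqrt(wx * wx + wy * wy);
    double f = (th > 1e-12) ? P.r.eval(th, 0) / th : 1.0;
    px = P.cx + f * wx; py = P.cy + f * wy;
    z = P.h.eval(th, 0);
  }
  if (M.has_chi()) z += M.chi(px, py);
  out[0] = px; out[1] = py; out[2] = z;
}

// J rows are d(x,y,z)/d(u1,u2); row-major: J[0],J[1] = dx/du; J[2],J[3] = dy/du;
// J[4],J[5] = dz/du.
void surf_jac(const Membrane& M, double u1, double u2, double J[6]) {
  int j = M.find(u1, u2);
  double JP11 = 1, JP12 = 0, JP22 = 1;    // horizontal Jacobian (symmetric)
  double zx = 0, zy = 0, px = u1, py = u2;
  if (j >= 0) {
    const Papilla& P = M.pap[j];
    double wx = u1 - P.cx, wy = u2 - P.cy;
    double th = std::sqrt(wx * wx + wy * wy);
    if (th > 1e-9) {
      double a = wx / th, b = wy / th;
      double rp = P.r.eval(th, 1);
      double rr = P.r.eval(th, 0) / th;
      double hp = P.h.eval(th, 1);
      JP11 = rp * a * a + rr * b * b;
      JP12 = (rp - rr) * a * b;
      JP22 = rp * b * b + rr * a * a;
      zx = hp * a; zy = hp * b;
      px = P.cx + rr * wx; py = P.cy + rr * wy;
    }
  }
  if (M.has_chi()) {
    double gx, gy;
    M.chi_grad(px, py, gx, gy);
    zx += JP11 * gx + JP12 * gy;
    zy += JP12 * gx + JP22 * gy;
  }
  J[0] = JP11; J[1] = JP12;
  J[2] = JP12; J[3] = JP22;
  J[4] = zx;   J[5] = zy;
}

void metric_at(const Membrane& M, double u1, double u2, double g[3]) {
  double J[6];
  surf_jac(M, u1, u2, J);
  g[0] = J[0] * J[0] + J[2] * J[2] + J[4] * J[4];
  g[1] = J[0] * J[1] + J[2] * J[3] + J[4] * J[5];
  g[2] = J[1] * J[1] + J[3] * J[3] + J[5] * J[5];
}

// chi active anywhere within `margin` of u (in the horizontal plane)?
static bool chi_active(const Membrane& M, double x, double y, double margin) {
  for (const Bump& b : M.bumps) {
    double dx = x - b.cx, dy = y - b.cy;
    if (std::sqrt(dx * dx + dy * dy) < b.rad + margin) return true;
  }
  return false;
}

// Christoffel symbols of the chart metric.  G = {G^1_11, G^1_12, G^1_22,
// G^2_11, G^2_12, G^2_22}.  Analytic from spline derivatives away from the
// coarse deformation; finite differences of the metric where chi is active.
void christoffel_at(const Membrane& M, double u1, double u2, double G[6]) {
  for (int k = 0; k < 6; ++k) G[k] = 0.0;
  const bool chi_here = M.has_chi() && chi_active(M, u1, u2, 2.0);
  int j = M.find(u1, u2);
  if (j < 0 && !chi_here) return;          // flat: all symbols vanish

  double g[3], dg1[3], dg2[3];             // dgk = d g / d u_k
  metric_at(M, u1, u2, g);

  if (!chi_here) {
    const Papilla& P = M.pap[j];
    double wx = u1 - P.cx, wy = u2 - P.cy;
    double th = std::sqrt(wx * wx + wy * wy);
    if (th < 1e-7) return;                 // metric is C^2-flat at the apex
    double a = wx / th, b = wy / th;
    double r = P.r.eval(th, 0), rp = P.r.eval(th, 1), rpp = P.r.eval(th, 2);
    double hp = P.h.eval(th, 1), hpp = P.h.eval(th, 2);
    double E = rp * rp + hp * hp;
    double Gt = (r / th) * (r / th);
    double Ep = 2.0 * (rp * rpp + hp * hpp);
    double Gtp = 2.0 * (r / th) * (rp * th - r) / (th * th);
    // M = u u^T; dM/du_k = (Ek u^T + u Ek^T)/th with Ek = e_k - u_k u
    double M11 = a * a, M12 = a * b, M22 = b * b;
    double E1x = 1.0 - a * a, E1y = -a * b;      // E1 = e1 - a*(a,b)
    double E2x = -a * b, E2y = 1.0 - b * b;
    // k = 1
    {
      double dM11 = 2.0 * E1x * a / th;
      double dM12 = (E1x * b + a * E1y) / th;
      double dM22 = 2.0 * E1y * b / th;
      dg1[0] = Gtp * a + (Ep - Gtp) * a * M11 + (E - Gt) * dM11;
      dg1[1] = (Ep - Gtp) * a * M12 + (E - Gt) * dM12;
      dg1[2] = Gtp * a + (Ep - Gtp) * a * M22 + (E - Gt) * dM22;
    }
    // k = 2
    {
      double dM11 = 2.0 * E2x * a / th;
      double dM12 = (E2x * b + a * E2y) / th;
      double dM22 = 2.0 * E2y * b / th;
      dg2[0] = Gtp * b + (Ep - Gtp) * b * M11 + (E - Gt) * dM11;
      dg2[1] = (Ep - Gtp) * b * M12 + (E - Gt) * dM12;
      dg2[2] = Gtp * b + (Ep - Gtp) * b * M22 + (E - Gt) * dM22;
    }
  } else {
    const double h = 1e-3;
    double gp[3], gm[3];
    metric_at(M, u1 + h, u2, gp); metric_at(M, u1 - h, u2, gm);
    for (int k = 0; k < 3; ++k) dg1[k] = (gp[k] - gm[k]) / (2.0 * h);
    metric_at(M, u1, u2 + h, gp); metric_at(M, u1, u2 - h, gm);
    for (int k = 0; k < 3; ++k) dg2[k] = (gp[k] - gm[k]) / (2.0 * h);
  }

  double det = g[0] * g[2] - g[1] * g[1];
  double gi11 = g[2] / det, gi12 = -g[1] / det, gi22 = g[0] / det;
  // dg[k][i][j] with symmetric storage {11,12,22}
  auto dgk = [&](int k, int i, int jj) -> double {
    const double* d = (k == 0) ? dg1 : dg2;
    int idx = (i == 0 && jj == 0) ? 0 : ((i == 1 && jj == 1) ? 2 : 1);
    return d[idx];
  };
  for (int kk = 0; kk < 2; ++kk) {
    for (int i = 0; i < 2; ++i) {
      for (int jj = i; jj < 2; ++jj) {
        double s = 0.0;
        for (int l = 0; l < 2; ++l) {
          double gil = (kk == 0)
            ? (l == 0 ? gi11 : gi12)
            : (l == 0 ? gi12 : gi22);
          s += gil * (dgk(i, jj, l) + dgk(jj, i, l) - dgk(l, i, jj));
        }
        s *= 0.5;
        int pos = kk * 3 + ((i == 0 && jj == 0) ? 0 : (i + jj == 1 ? 1 : 2));
        G[pos] = s;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// geodesic integration: classic RK4 on (u, v), substeps bounded so each
// substep's chart displacement is <= max_disp.

static void geo_accel(const Membrane& M, const double u[2], const double v[2],
                      double a[2]) {
  double G[6];
  christoffel_at(M, u[0], u[1], G);
  a[0] = -(G[0] * v[0] * v[0] + 2.0 * G[1] * v[0] * v[1] + G[2] * v[1] * v[1]);
  a[1] = -(G[3] * v[0] * v[0] + 2.0 * G[4] * v[0] * v[1] + G[5] * v[1] * v[1]);
}

int geodesic_advance(const Membrane& M, double u[2], double v[2], double dt,
                     double max_disp) {
  double g[3];
  metric_at(M, u[0], u[1], g);
  double speed = std::sqrt(g[0] * v[0] * v[0] + 2.0 * g[1] * v[0] * v[1] +
                           g[2] * v[1] * v[1]);   // surface speed (geodesics preserve it)
  if (speed * dt < 1e-14) return 0;
  int nsub = std::max(1, (int)std::ceil(speed * dt / max_disp));
  double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    double k1u[2], k1v[2], k2u[2], k2v[2], k3u[2], k3v[2], k4u[2], k4v[2];
    double ut[2], vt[2];
    geo_accel(M, u, v, k1v); k1u[0] = v[0]; k1u[1] = v[1];
    ut[0] = u[0] + 0.5 * h * k1u[0]; ut[1] = u[1] + 0.5 * h * k1u[1];
    vt[0] = v[0] + 0.5 * h * k1v[0]; vt[1] = v[1] + 0.5 * h * k1v[1];
    geo_accel(M, ut, vt, k2v); k2u[0] = vt[0]; k2u[1] = vt[1];
    ut[0] = u[0] + 0.5 * h * k2u[0]; ut[1] = u[1] + 0.5 * h * k2u[1];
    vt[0] = v[0] + 0.5 * h * k2v[0]; vt[1] = v[1] + 0.5 * h * k2v[1];
    geo_accel(M, ut, vt, k3v); k3u[0] = vt[0]; k3u[1] = vt[1];
    ut[0] = u[0] + h * k3u[0]; ut[1] = u[1] + h * k3u[1];
    vt[0] = v[0] + h * k3v[0]; vt[1] = v[1] + h * k3v[1];
    geo_accel(M, ut, vt, k4v); k4u[0] = vt[0]; k4u[1] = vt[1];
    for (int d = 0; d < 2; ++d) {
      u[d] += h / 6.0 * (k1u[d] + 2.0 * k2u[d] + 2.0 * k3u[d] + k4u[d]);
      v[d] += h / 6.0 * (k1v[d] + 2.0 * k2v[d] + 2.0 * k3v[d] + k4v[d]);
    }
    if (u[0] < 0 || u[0] > M.Lx || u[1] < 0 || u[1] > M.Ly) return 1;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// inverse chart: 3D surface point -> chart coordinates

// Invert r(theta) = s by safeguarded Newton (r is strictly increasing).
static double invert_r(const PPoly& r, double R, double s) {
  if (s <= 0) return 0.0;
  if (s >= R) return R;
  double lo = 0.0, hi = R, th = s;
  for (int it = 0; it < 60; ++it) {
    double f = r.eval(th, 0) - s;
    if (std::fabs(f) < 1e-11) break;
    if (f > 0) hi = th; else lo = th;
    double dp = r.eval(th, 1);
    double step = (dp > 1e-8) ? f / dp : 0.0;
    th -= step;
    if (th <= lo || th >= hi || dp <= 1e-8) th = 0.5 * (lo + hi);
  }
  return th;
}

void snap_to_surface(const Membrane& M, double x, double y, double u[2]) {
  int j = M.find(x, y);
  if (j < 0) { u[0] = x; u[1] = y; return; }
  const Papilla& P = M.pap[j];
  double wx = x - P.cx, wy = y - P.cy;
  double s = std::sqrt(wx * wx + wy * wy);
  double th = invert_r(P.r, P.R, s);
  if (s > 1e-12) {
    u[0] = P.cx + th * wx / s; u[1] = P.cy + th * wy / s;
  } else {
    u[0] = P.cx; u[1] = P.cy;
  }
}

int chart_fwd_pt(const Membrane& M, double x, double y, double z, double tol,
                 double u[2]) {
  snap_to_surface(M, x, y, u);
  double p[3];
  surf_point(M, u[0], u[1], p);
  double dz = z - p[2];
  return (std::fabs(dz) > tol) ? 1 : 0;
}

// ---------------------------------------------------------------------------
// R interface

// [[Rcpp::export(name = ".cpp_surface_points")]]
NumericMatrix cpp_surface_points(List membrane, NumericMatrix u) {
  Membrane M = parse_membrane(membrane);
  NumericMatrix out(u.nrow(), 3);
  double p[3];
  for (int i = 0; i < u.nrow(); ++i) {
    surf_point(M, u(i, 0), u(i, 1), p);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_chart_forward")]]
List cpp_chart_forward(List membrane, NumericMatrix x, double tol) {
  Membrane M = parse_membrane(membrane);
  NumericMatrix out(x.nrow(), 2);
  IntegerVector off(x.nrow());
  double u[2];
  for (int i = 0; i < x.nrow(); ++i) {
    off[i] = chart_fwd_pt(M, x(i, 0), x(i, 1), x(i, 2), tol, u);
    out(i, 0) = u[0]; out(i, 1) = u[1];
  }
  return List::create(_["u"] = out, _["off_manifold"] = off);
}

// [[Rcpp::export(name = ".cpp_metric")]]
NumericVector cpp_metric(List membrane, double u1, double u2) {
  Membrane M = parse_membrane(membrane);
  double g[3];
  metric_at(M, u1, u2, g);
  return NumericVector::create(g[0], g[1], g[2]);
}

// [[Rcpp::export(name = ".cpp_jacobian")]]
NumericMatrix cpp_jacobian(List membrane, double u1, double u2) {
  Membrane M = parse_membrane(membrane);
  double J[6];
  surf_jac(M, u1, u2, J);
  NumericMatrix out(3, 2);
  out(0, 0) = J[0]; out(0, 1) = J[1];
  out(1, 0) = J[2]; out(1, 1) = J[3];
  out(2, 0) = J[4]; out(2, 1) = J[5];
  return out;
}

// [[Rcpp::export(name = ".cpp_christoffel")]]
NumericVector cpp_christoffel(List membrane, double u1, double u2) {
  Membrane M = parse_membrane(membrane);
  double G[6];
  christoffel_at(M, u1, u2, G);
  return NumericVector(G, G + 6);
}

// [[Rcpp::export(name = ".cpp_geodesic_step")]]
List cpp_geodesic_step(List membrane, NumericVector u0, NumericVector v0,
                       double dt, double max_disp) {
  Membrane M = parse_membrane(membrane);
  double u[2] = { u0[0], u0[1] }, v[2] = { v0[0], v0[1] };
  int st = geodesic_advance(M, u, v, dt, max_disp);
  return List::create(_["u"] = NumericVector::create(u[0], u[1]),
                      _["v"] = NumericVector::create(v[0], v[1]),
                      _["exited"] = (st == 1));
}
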