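#include "nevosim.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// One iteration of the agent scheme: density update -> movement (all cells)
// -> divisions / differentiation -> emigrations -> discard domain exits.
// Positions in micrometres, time in days.  Uses R's RNG (single stream).

namespace {

struct Table {
  std::vector<double> y;
  double xmax = 1.0;
  double at(double x) const {          // linear interpolation on [0, xmax]
    if (y.empty()) return 1.0;
    const int n = (int)y.size();
    if (x <= 0) return y.front();
    if (x >= xmax) return y.back();
    double t = x / xmax * (n - 1);
    int i = std::min(n - 2, (int)t);
    double f = t - i;
    return y[i] * (1 - f) + y[i + 1] * f;
  }
  double at_idx(int g) const {         // lookup by integer index, clamped
    if (y.empty()) return 1.0;
    if (g < 0) g = 0;
    if (g >= (int)y.size()) g = (int)y.size() - 1;
    return y[(size_t)g];
  }
};

Table parse_table(const List& p, const char* name, double xmax) {
  Table t;
  t.xmax = xmax;
  if (p.containsElementNamed(name)) {
    NumericVector v = p[name];
    t.y.assign(v.begin(), v.end());
  }
  return t;
}

struct Params {
  double dt, D, K, q0, p0_nest, p0_default, sigma_p0, sigma_radius;
  double vext_mag, tip_alt, vderm_vert, vderm_horiz;
  double offset_frac, max_substep, chart_tol;
  int emitted_proliferate, tangent_rotate;
  Table A, B, Q, Rgen, Ga, Gr, Ha, Hr, Anest, Bnest, Semig, Fa, Fr;
  double fa_cutoff, fr_cutoff;
};

Params parse_params(const List& p) {
  Params P;
  P.dt = as<double>(p["dt"]);
  P.D = as<double>(p["D"]);
  P.K = as<double>(p["K"]);
  P.q0 = as<double>(p["q0"]);
  P.p0_nest = as<double>(p["p0_nest"]);
  P.p0_default = as<double>(p["p0_default"]);
  P.sigma_p0 = as<double>(p["sigma_p0"]);
  P.sigma_radius = as<double>(p["sigma_radius"]);
  P.vext_mag = as<double>(p["vext_mag"]);
  P.tip_alt = as<double>(p["tip_alt"]);
  P.vderm_vert = as<double>(p["vderm_vert"]);
  P.vderm_horiz = as<double>(p["vderm_horiz"]);
  P.offset_frac = as<double>(p["offset_frac"]);
  P.max_substep = as<double>(p["max_substep"]);
  P.chart_tol = as<double>(p["chart_tol"]);
  P.emitted_proliferate = as<int>(p["emitted_proliferate"]);
  P.tangent_rotate = as<int>(p["tangent_rotate"]);
  P.A = parse_table(p, "A_tab", 60);
  P.B = parse_table(p, "B_tab", 1.0);
  P.Q = parse_table(p, "Q_tab", 1.0);
  P.Rgen = parse_table(p, "Rgen_tab", 60);
  P.Ga = parse_table(p, "Ga_tab", 1.0);
  P.Gr = parse_table(p, "Gr_tab", 1.0);
  P.Ha = parse_table(p, "Ha_tab", 60);
  P.Hr = parse_table(p, "Hr_tab", 60);
  P.Anest = parse_table(p, "Anest_tab", 1.0);
  P.Bnest = parse_table(p, "Bnest_tab", 1.0);
  P.Semig = parse_table(p, "s_tab", 1.0);
  P.fa_cutoff = as<double>(p["fa_cutoff"]);
  P.fr_cutoff = as<double>(p["fr_cutoff"]);
  P.Fa = parse_table(p, "Fa_tab", std::max(P.fa_cutoff, 1e-6));
  P.Fr = parse_table(p, "Fr_tab", std::max(P.fr_cutoff, 1e-6));
  return P;
}

inline double omega(double gap) {
  if (gap < 0) gap = 0;
  if (gap >= 100.0) return 0.0;
  double t = 1.0 - gap / 100.0;
  return 0.02 * t * t;
}

struct Cells {
  std::vector<double> x, y, z, u1, u2, radius, p0;
  std::vector<int> id, gen, strain, sgen, nested;
  size_t n() const { return x.size(); }
};

struct Nbr { double gap, ux, uy, uz; int j; };

}  // namespace

// [[Rcpp::export(name = ".cpp_sim_step")]]
List cpp_sim_step(List state, List membrane, List params) {
  Membrane M = parse_membrane(membrane);
  Params P = parse_params(params);
  const double dt = P.dt;

  Cells C;
  {
    NumericVector x = state["x"], y = state["y"], z = state["z"],
      uu1 = state["u1"], uu2 = state["u2"], rad = state["radius"],
      p0 = state["p0"];
    IntegerVector id = state["id"], gen = state["generation"],
      strain = state["strain"], sgen = state["strain_generation"];
    LogicalVector nested = state["nested"];
    C.x.assign(x.begin(), x.end()); C.y.assign(y.begin(), y.end());
    C.z.assign(z.begin(), z.end());
    C.u1.assign(uu1.begin(), uu1.end()); C.u2.assign(uu2.begin(), uu2.end());
    C.radius.assign(rad.begin(), rad.end());
    C.p0.assign(p0.begin(), p0.end());
    C.id.assign(id.begin(), id.end()); C.gen.assign(gen.begin(), gen.end());
    C.strain.assign(strain.begin(), strain.end());
    C.sgen.assign(sgen.begin(), sgen.end());
    C.nested.assign(nested.begin(), nested.end());
  }
  int next_id = as<int>(state["next_id"]);
  int next_strain = as<int>(state["next_strain"]);
  const size_t n0 = C.n();

  double rmax = 1.0;
  for (double r : C.radius) rmax = std::max(rmax, r);
  const bool forces_on = (P.fa_cutoff > 0) || (P.fr_cutoff > 0);
  double cutoff = 100.0 + 2.0 * rmax;       // omega support dominates
  cutoff = std::max(cutoff, std::max(P.fa_cutoff, P.fr_cutoff) + 2.0 * rmax);

  // ---- neighbor grid on horizontal coordinates (old positions) -----------
  // Fine bins scanned ring by ring outward, so that the density pass can
  // stop as soon as the clamp value 1 is reached and the movement pass only
  // gathers neighbors within its (usually short) interaction horizon.
  const std::vector<double> xo = C.x, yo = C.y, zo = C.z, ro = C.radius;
  const double bin = std::max(36.0, 2.0 * rmax + 2.0);
  double xmin = 0, ymin = 0;
  int ngx = 1, ngy = 1;
  std::vector<int> head, nxt(n0, -1);
  {
    double xmax_ = M.Lx, ymax_ = M.Ly;
    for (size_t i = 0; i < n0; ++i) {       // nested cells may drift outside
      xmin = std::min(xmin, xo[i]); xmax_ = std::max(xmax_, xo[i]);
      ymin = std::min(ymin, yo[i]); ymax_ = std::max(ymax_, yo[i]);
    }
    ngx = std::max(1, (int)std::floor((xmax_ - xmin) / bin) + 1);
    ngy = std::max(1, (int)std::floor((ymax_ - ymin) / bin) + 1);
    head.assign((size_t)ngx * ngy, -1);
    for (size_t i = 0; i < n0; ++i) {
      int gx = std::min(ngx - 1, std::max(0, (int)((xo[i] - xmin) / bin)));
      int gy = std::min(ngy - 1, std::max(0, (int)((yo[i] - ymin) / bin)));
      size_t b = (size_t)gy * ngx + gx;
      nxt[i] = head[b]; head[b] = (int)i;
    }
  }
  // visit all cells j != i within 3D distance <= dist_lim of cell i,
  // ring by ring; the visitor returns false to stop early
  auto scan = [&](size_t i, double dist_lim, auto&& visit) {
    int gx = std::min(ngx - 1, std::max(0, (int)((xo[i] - xmin) / bin)));
    int gy = std::min(ngy - 1, std::max(0, (int)((yo[i] - ymin) / bin)));
    int nring = (int)(dist_lim / bin) + 1;
    for (int ring = 0; ring <= nring; ++ring) {
      for (int bx = gx - ring; bx <= gx + ring; ++bx) {
        if (bx < 0 || bx >= ngx) continue;
        for (int by = gy - ring; by <= gy + ring; ++by) {
          if (by < 0 || by >= ngy) continue;
          if (ring > 0 && std::abs(bx - gx) != ring && std::abs(by - gy) != ring)
            continue;                        // interior of the ring already done
          for (int j = head[(size_t)by * ngx + bx]; j >= 0; j = nxt[j]) {
            if ((size_t)j == i) continue;
            double dx = xo[j] - xo[i], dy = yo[j] - yo[i], dz = zo[j] - zo[i];
            double dist2 = dx * dx + dy * dy + dz * dz;
            if (dist2 > dist_lim * dist_lim) continue;
            if (!visit((size_t)j, dx, dy, dz, dist2)) return;
          }
        }
      }
    }
  };
  // collect neighbors with gap <= horizon (3D gap distance)
  auto for_neighbors = [&](size_t i, double horizon, std::vector<Nbr>& out) {
    out.clear();
    scan(i, horizon + ro[i] + rmax,
         [&](size_t j, double dx, double dy, double dz, double dist2) {
      double lim = horizon + ro[i] + ro[j];
      if (dist2 < lim * lim) {
        double dist = std::sqrt(dist2);
        Nbr nb;
        nb.gap = dist - ro[i] - ro[j]; nb.j = (int)j;
        if (dist > 1e-12) {
          nb.ux = dx / dist; nb.uy = dy / dist; nb.uz = dz / dist;
        } else {                             // coincident: random direction
          double a = ::unif_rand() * 2.0 * M_PI, c = 2.0 * ::unif_rand() - 1;
          double s = std::sqrt(std::max(0.0, 1 - c * c));
          nb.ux = s * std::cos(a); nb.uy = s * std::sin(a); nb.uz = c;
        }
        out.push_back(nb);
      }
      return true;
    });
  };

  // ---- density (once per step, before movement) ---------------------------
  // early exit at the clamp value 1 (weights are non-negative)
  std::vector<double> rho(n0, 0.0);
  for (size_t i = 0; i < n0; ++i) {
    double s = 0.0;
    scan(i, 100.0 + ro[i] + rmax,
         [&](size_t j, double, double, double, double dist2) {
      s += omega(std::sqrt(dist2) - ro[i] - ro[j]);
      return s < 1.0;
    });
    rho[i] = std::min(1.0, s);
  }

  // ---- movement ----------------------------------------------------------
  std::vector<char> dead(n0, 0);
  int n_exit = 0;
  {
    std::vector<Nbr> nbrs;
    for (size_t i = 0; i < n0; ++i) {
      const double sig =
        std::sqrt(2.0 * P.D * P.Q.at(rho[i]) * P.Rgen.at_idx(C.gen[i]) / dt);
      double vx = sig * ::norm_rand(), vy = sig * ::norm_rand(),
             vz = sig * ::norm_rand();
      if (P.vext_mag > 0) {                 // altitude-scaled downward force
        double sc = (P.tip_alt > 0) ?
          std::min(1.0, std::max(0.0, zo[i] / P.tip_alt)) : 1.0;
        vz -= P.vext_mag * sc;
      }
      // neighbor horizon: collision reach of the current velocity, plus the
      // force cutoffs when intercellular forces are active
      double vmag = std::sqrt(vx * vx + vy * vy + vz * vz);
      double horizon = vmag * dt + 0.5;
      if (forces_on)
        horizon = std::max(horizon + 2.0,
                           std::max(P.fa_cutoff, P.fr_cutoff) + vmag * dt);
      for_neighbors(i, std::min(horizon, cutoff), nbrs);
      if (forces_on) {
        for (const Nbr& nb : nbrs) {
          double gp = std::max(0.0, nb.gap);
          bool same = C.nested[i] && C.nested[nb.j] &&
            C.strain[i] == C.strain[nb.j];
          double f = 0.0;
          if (same && P.fa_cutoff > 0 && gp < P.fa_cutoff)
            f += P.Fa.at(gp) * P.Ga.at(rho[i]) * P.Ha.at_idx(C.gen[i]);
          if (!same && (C.nested[i] || C.nested[nb.j]) &&
              P.fr_cutoff > 0 && gp < P.fr_cutoff)
            f -= P.Fr.at(gp) * P.Gr.at(rho[i]) * P.Hr.at_idx(C.gen[i]);
          vx += f * nb.ux; vy += f * nb.uy; vz += f * nb.uz;
        }
        // forces may have extended the collision reach
        double vmag2 = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (vmag2 * dt + 0.5 > horizon)
          for_neighbors(i, std::min(vmag2 * dt + 0.5, cutoff), nbrs);
      }
      // collision corrector: neighbors by ascending gap, passes repeated
      // towards a fixpoint so no single-pass leak lets conflicting
      // constraints pile overlap up (the iterative application that keeps
      // total overlap bounded).  Only neighbors within the initial
      // velocity's reach are considered: farther ones cannot trigger on the
      // uncorrected vector, and corrections that would push past them are
      // themselves bounded by nearer constraints.
      {
        double vm = std::sqrt(vx * vx + vy * vy + vz * vz);
        double reach = vm * dt + 1e-9;
        std::vector<Nbr> coll;
        coll.reserve(nbrs.size());
        for (const Nbr& nb : nbrs)
          if (nb.gap < reach) coll.push_back(nb);
        std::sort(coll.begin(), coll.end(),
                  [](const Nbr& a, const Nbr& b) { return a.gap < b.gap; });
        for (int pass = 0; pass < 6; ++pass) {
          bool changed = false;
          for (const Nbr& nb : coll) {
            double proj = nb.ux * vx + nb.uy * vy + nb.uz * vz;
            if (nb.gap < proj * dt - 1e-12) {
              double corr = (proj * dt - nb.gap) * P.K / dt;
              vx -= corr * nb.ux; vy -= corr * nb.uy; vz -= corr * nb.uz;
              changed = true;
            }
          }
          if (!changed) break;
        }
      }
      if (C.nested[i]) {
        // unconstrained Euler step with dermal exclusion
        double vdx = 0, vdy = 0, vdz = 0;
        if (zo[i] < 0) {
          vdz = P.vderm_vert;
        } else {
          int jp = M.find(xo[i], yo[i]);
          if (jp >= 0) {
            const Papilla& PP = M.pap[jp];
            double wx = xo[i] - PP.cx, wy = yo[i] - PP.cy;
            double s = std::sqrt(wx * wx + wy * wy);
            double u[2];
            snap_to_surface(M, xo[i], yo[i], u);
            double p3[3];
            surf_point(M, u[0], u[1], p3);
            if (zo[i] < p3[2]) {            // inside the papilla body
              if (s > 1e-9) {
                vdx = P.vderm_horiz * wx / s; vdy = P.vderm_horiz * wy / s;
              } else {
                double a = ::unif_rand() * 2.0 * M_PI;
                vdx = P.vderm_horiz * std::cos(a);
                vdy = P.vderm_horiz * std::sin(a);
              }
            }
          }
        }
        C.x[i] = xo[i] + dt * (vx + vdx);
        C.y[i] = yo[i] + dt * (vy + vdy);
        C.z[i] = zo[i] + dt * (vz + vdz);
        if (C.x[i] < 0 || C.x[i] > M.Lx || C.y[i] < 0 || C.y[i] > M.Ly) {
          dead[i] = 1; ++n_exit;
        }
      } else {
        // constrained: tangent projection -> pushforward -> geodesic
        double J[6];
        surf_jac(M, C.u1[i], C.u2[i], J);
        double nx = J[2] * J[5] - J[4] * J[3];
        double ny = J[4] * J[1] - J[0] * J[5];
        double nz = J[0] * J[3] - J[2] * J[1];
        double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
        nx /= nn; ny /= nn; nz /= nn;
        double dot = vx * nx + vy * ny + vz * nz;
        double tx = vx - dot * nx, ty = vy - dot * ny, tz = vz - dot * nz;
        if (P.tangent_rotate) {
          double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
          double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
          if (tn > 1e-12) { tx *= vn / tn; ty *= vn / tn; tz *= vn / tn; }
        }
        // vbar = g^{-1} J^T vtan
        double b1 = J[0] * tx + J[2] * ty + J[4] * tz;
        double b2 = J[1] * tx + J[3] * ty + J[5] * tz;
        double g11 = J[0] * J[0] + J[2] * J[2] + J[4] * J[4];
        double g12 = J[0] * J[1] + J[2] * J[3] + J[4] * J[5];
        double g22 = J[1] * J[1] + J[3] * J[3] + J[5] * J[5];
        double det = g11 * g22 - g12 * g12;
        double v2[2] = { (g22 * b1 - g12 * b2) / det,
                         (g11 * b2 - g12 * b1) / det };
        double u[2] = { C.u1[i], C.u2[i] };
        int st = geodesic_advance(M, u, v2, dt, P.max_substep);
        if (st == 1) { dead[i] = 1; ++n_exit; continue; }
        C.u1[i] = u[0]; C.u2[i] = u[1];
        double p3[3];
        surf_point(M, u[0], u[1], p3);
        C.x[i] = p3[0]; C.y[i] = p3[1]; C.z[i] = p3[2];
      }
    }
  }

  // ---- division / differentiation ----------------------------------------
  int n_div = 0, n_diff = 0;
  std::vector<int> diff_strain, diff_founder;
  std::vector<double> rho_all(rho);
  {
    const size_t nmov = C.n();
    for (size_t i = 0; i < nmov; ++i) {
      if (dead[i]) continue;
      double damp;
      if (C.nested[i])
        damp = P.Anest.at_idx(C.sgen[i]) * P.Bnest.at(rho_all[i]);
      else
        damp = P.A.at_idx(C.gen[i]) * P.B.at(rho_all[i]);
      double pdiv = std::exp(damp * C.p0[i] * dt) - 1.0;
      if (pdiv > 1.0)
        stop("division probability exceeds 1; reduce p0*dt");
      if (::unif_rand() >= pdiv) continue;
      ++n_div;
      // parent slot becomes daughter 1, daughter 2 appended
      bool differentiate = (!C.nested[i]) && (P.q0 > 0) &&
        (::unif_rand() < P.q0);
      int g_new = C.gen[i] + 1;
      int strain_new = C.strain[i], sgen_new = C.sgen[i];
      bool nested_new = C.nested[i] != 0;
      if (differentiate) {
        strain_new = next_strain++;
        sgen_new = 1;
        nested_new = true;
        ++n_diff;
        diff_strain.push_back(strain_new);
        diff_founder.push_back(C.id[i]);
      } else if (C.nested[i]) {
        sgen_new = C.sgen[i] + 1;
      }
      double base_p0 = differentiate ? P.p0_nest : C.p0[i];
      double p0a = std::max(0.0, base_p0 + P.sigma_p0 * ::norm_rand());
      double p0b = std::max(0.0, base_p0 + P.sigma_p0 * ::norm_rand());
      double ra = std::max(0.5, C.radius[i] + P.sigma_radius * ::norm_rand());
      double rb = std::max(0.5, C.radius[i] + P.sigma_radius * ::norm_rand());
      double off = P.offset_frac * C.radius[i];
      double xa[3], xb[3], ua[2], ub[2];
      if (nested_new) {
        double aang = ::unif_rand() * 2.0 * M_PI, c = 2.0 * ::unif_rand() - 1;
        double s = std::sqrt(std::max(0.0, 1 - c * c));
        double ox = off * s * std::cos(aang), oy = off * s * std::sin(aang),
               oz = off * c;
        xa[0] = C.x[i] + ox; xa[1] = C.y[i] + oy; xa[2] = C.z[i] + oz;
        xb[0] = C.x[i] - ox; xb[1] = C.y[i] - oy; xb[2] = C.z[i] - oz;
        ua[0] = ua[1] = ub[0] = ub[1] = 0;
      } else {
        double aang = ::unif_rand() * 2.0 * M_PI;
        double ox = off * std::cos(aang), oy = off * std::sin(aang);
        auto clampu = [&](double* u) {
          u[0] = std::min(M.Lx - 1e-9, std::max(1e-9, u[0]));
          u[1] = std::min(M.Ly - 1e-9, std::max(1e-9, u[1]));
        };
        ua[0] = C.u1[i] + ox; ua[1] = C.u2[i] + oy; clampu(ua);
        ub[0] = C.u1[i] - ox; ub[1] = C.u2[i] - oy; clampu(ub);
        surf_point(M, ua[0], ua[1], xa);
        surf_point(M, ub[0], ub[1], xb);
      }
      // daughter 1 replaces the parent
      C.x[i] = xa[0]; C.y[i] = xa[1]; C.z[i] = xa[2];
      C.u1[i] = ua[0]; C.u2[i] = ua[1];
      C.radius[i] = ra; C.p0[i] = p0a;
      C.id[i] = next_id++; C.gen[i] = g_new;
      C.strain[i] = strain_new; C.sgen[i] = sgen_new;
      C.nested[i] = nested_new ? 1 : 0;
      // daughter 2 appended
      C.x.push_back(xb[0]); C.y.push_back(xb[1]); C.z.push_back(xb[2]);
      C.u1.push_back(ub[0]); C.u2.push_back(ub[1]);
      C.radius.push_back(rb); C.p0.push_back(p0b);
      C.id.push_back(next_id++); C.gen.push_back(g_new);
      C.strain.push_back(strain_new); C.sgen.push_back(sgen_new);
      C.nested.push_back(nested_new ? 1 : 0);
      dead.push_back(0);
      rho_all.push_back(rho_all[i]);
    }
  }

  // ---- emigration ---------------------------------------------------------
  int n_emig = 0;
  {
    const size_t nn = C.n();
    for (size_t i = 0; i < nn; ++i) {
      if (dead[i] || !C.nested[i]) continue;
      double pe = 1.0 - std::exp(-P.Semig.at_idx(C.sgen[i]) * dt);
      if (::unif_rand() >= pe) continue;
      ++n_emig;
      C.nested[i] = 0;
      C.strain[i] = 0;
      C.sgen[i] = 0;
      C.p0[i] = P.emitted_proliferate ? P.p0_default : 0.0;
      // re-attach to the membrane surface at the current horizontal position
      if (C.x[i] < 0 || C.x[i] > M.Lx || C.y[i] < 0 || C.y[i] > M.Ly) {
        dead[i] = 1; ++n_exit; continue;
      }
      double u[2];
      snap_to_surface(M, C.x[i], C.y[i], u);
      double p3[3];
      surf_point(M, u[0], u[1], p3);
      C.u1[i] = u[0]; C.u2[i] = u[1];
      C.x[i] = p3[0]; C.y[i] = p3[1]; C.z[i] = p3[2];
    }
  }

  // ---- compact ------------------------------------------------------------
  Cells out;
  const size_t nn = C.n();
  out.x.reserve(nn);
  for (size_t i = 0; i < nn; ++i) {
    if (dead[i]) continue;
    out.x.push_back(C.x[i]); out.y.push_back(C.y[i]); out.z.push_back(C.z[i]);
    out.u1.push_back(C.u1[i]); out.u2.push_back(C.u2[i]);
    out.radius.push_back(C.radius[i]); out.p0.push_back(C.p0[i]);
    out.id.push_back(C.id[i]); out.gen.push_back(C.gen[i]);
    out.strain.push_back(C.strain[i]); out.sgen.push_back(C.sgen[i]);
    out.nested.push_back(C.nested[i]);
  }

  List st = List::create(
    _["id"] = wrap(out.id), _["x"] = wrap(out.x), _["y"] = wrap(out.y),
    _["z"] = wrap(out.z), _["u1"] = wrap(out.u1), _["u2"] = wrap(out.u2),
    _["radius"] = wrap(out.radius), _["generation"] = wrap(out.gen),
    _["strain"] = wrap(out.strain), _["strain_generation"] = wrap(out.sgen),
    _["nested"] = LogicalVector(out.nested.begin(), out.nested.end()),
    _["p0"] = wrap(out.p0),
    _["next_id"] = next_id, _["next_strain"] = next_strain);
  List ev = List::create(
    _["divisions"] = n_div, _["differentiations"] = n_diff,
    _["emigrations"] = n_emig, _["exits"] = n_exit,
    _["new_strains"] = wrap(diff_strain),
    _["new_strain_founders"] = wrap(diff_founder));
  return List::create(_["state"] = st, _["events"] = ev);
}
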