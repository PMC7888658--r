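#pragma once

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// Piecewise polynomial (Taylor form per interval) -- the internal
// representation of one B-spline shape-curve component.  Degree <= 5.
struct PPoly {
  std::vector<double> breaks;          // ascending, breaks.front() == 0
  std::vector<double> coef;            // 6 per interval, c0..c5 at left break

  double length() const { return breaks.back(); }

  double eval(double x, int d) const {
    const int m = (int)breaks.size() - 1;
    if (x <= breaks.front()) x = breaks.front();
    else if (x >= breaks[m]) x = breaks[m];
    int i = m - 1;
    for (int k = 1; k < m; ++k) {
      if (x < breaks[k]) { i = k - 1; break; }
    }
    const double dx = x - breaks[i];
    const double* c = &coef[6 * i];
    double acc = 0.0;
    for (int k = 5; k >= d; --k) {
      double f = 1.0;
      for (int j = 0; j < d; ++j) f *= (double)(k - j);
      acc = acc * dx + c[k] * f;
    }
    return acc;
  }
};

struct Papilla {
  double cx, cy, R, H;
  PPoly r, h;
};

struct Bump { double cx, cy, rad, amp; };

// Composite membrane: planar base plane z = 0 (plus coarse deformation
// field chi) with disjoint papilla charts.  Global chart coordinates u
// live in [0,Lx] x [0,Ly]; inside a papilla base disk u is the virtual
// radius coordinate (horizontal position is c + r(theta) * unit(u - c)).
struct Membrane {
  double Lx = 0, Ly = 0;
  std::vector<Papilla> pap;
  std::vector<Bump> bumps;
  PPoly prof;                          // unit bump profile, [0,1] -> [0,1]

  // papilla lookup grid
  double cell = 0; int ngx = 0, ngy = 0;
  std::vector<std::vector<int>> grid;

  bool has_chi() const { return !bumps.empty(); }

  void build_grid();
  int find(double x, double y) const;  // papilla whose base disk contains (x,y), -1 if none
  double chi(double x, double y) const;
  void chi_grad(double x, double y, double& gx, double& gy) const;
};

Membrane parse_membrane(const Rcpp::List& mem);

// geometry kernels (definitions in geometry.cpp)
void surf_point(const Membrane& M, double u1, double u2, double out[3]);
void surf_jac(const Membrane& M, double u1, double u2, double J[6]); // rows x,y,z
void metric_at(const Membrane& M, double u1, double u2, double g[3]); // g11,g12,g22
void christoffel_at(const Membrane& M, double u1, double u2, double G[6]);
int geodesic_advance(const Membrane& M, double u[2], double v[2], double dt,
                     double max_disp);          // 0 ok, 1 exited domain
int chart_fwd_pt(const Membrane& M, double x, double y, double z, double tol,
                 double u[2]);                  // 0 ok, 1 off-manifold
void snap_to_surface(const Membrane& M, double x, double y, double u[2]);
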