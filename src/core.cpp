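#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Honeycomb lattice convention used throughout: primitive vectors
//   a1 = (sqrt(3) b, 0), a2 = (sqrt(3) b / 2, 1.5 b)
// with a two-atom basis at (0, 0) and (0, b); all atoms in the z = 0 plane.
// Enumerating the infinite lattice inside an xy disk is exact for periodic
// boxes built from integer multiples of (a1, a2), and is how both the VDW
// sum and the SASA patch see the surface.

static inline void lattice_sites_in_disk(double cx, double cy, double r,
                                         double b,
                                         std::vector<double> &xs,
                                         std::vector<double> &ys) {
  const double a1x = std::sqrt(3.0) * b;
  const double a2x = 0.5 * std::sqrt(3.0) * b, a2y = 1.5 * b;
  // conservative integer ranges covering the disk in fractional coordinates
  const double margin = r / (1.5 * b) + 2.0;
  const double det = a1x * a2y;
  const double fi = (cx * a2y - cy * a2x) / det;
  const double fj = cy / a2y;
  const int i0 = (int)std::floor(fi - margin), i1 = (int)std::ceil(fi + margin);
  const int j0 = (int)std::floor(fj - margin), j1 = (int)std::ceil(fj + margin);
  const double r2 = r * r;
  for (int i = i0; i <= i1; ++i) {
    for (int j = j0; j <= j1; ++j) {
      const double ox = i * a1x + j * a2x;
      const double oy = j * a2y;
      for (int k = 0; k < 2; ++k) {
        const double x = ox, y = oy + (k == 0 ? 0.0 : b);
        const double dx = x - cx, dy = y - cy;
        if (dx * dx + dy * dy <= r2) {
          xs.push_back(x);
          ys.push_back(y);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".graphene_disk")]]
NumericMatrix graphene_disk(double cx, double cy, double radius, double bond) {
  std::vector<double> xs, ys;
  lattice_sites_in_disk(cx, cy, radius, bond, xs, ys);
  NumericMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
    out(i, 2) = 0.0;
  }
  return out;
}

// [[Rcpp::export(name = ".min_surface_dist")]]
NumericVector min_surface_dist(NumericMatrix coords, double bond) {
  const int n = coords.nrow();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    std::vector<double> xs, ys;
    lattice_sites_in_disk(coords(a, 0), coords(a, 1), 2.1 * bond, bond, xs, ys);
    double best = R_PosInf;
    const double z = coords(a, 2);
    for (size_t s = 0; s < xs.size(); ++s) {
      const double dx = coords(a, 0) - xs[s], dy = coords(a, 1) - ys[s];
      const double d2 = dx * dx + dy * dy + z * z;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

static inline double lj(double r2, double eps, double rmin) {
  const double s2 = (rmin * rmin) / r2;
  const double s6 = s2 * s2 * s2;
  return eps * (s6 * s6 - 2.0 * s6);
}

// [[Rcpp::export(name = ".vdw_lattice")]]
double vdw_lattice(NumericMatrix coords, NumericVector eps,
                   NumericVector rmin_half, double surf_eps,
                   double surf_rmin_half, double bond, double cutoff) {
  const int n = coords.nrow();
  const double cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int a = 0; a < n; ++a) {
    const double z = coords(a, 2);
    if (std::fabs(z) >= cutoff) continue;
    const double disk = std::sqrt(cut2 - z * z);
    std::vector<double> xs, ys;
    lattice_sites_in_disk(coords(a, 0), coords(a, 1), disk, bond, xs, ys);
    const double eab = std::sqrt(eps[a] * surf_eps);
    const double rmin = rmin_half[a] + surf_rmin_half;
    for (size_t s = 0; s < xs.size(); ++s) {
      const double dx = coords(a, 0) - xs[s], dy = coords(a, 1) - ys[s];
      const double r2 = dx * dx + dy * dy + z * z;
      if (r2 > cut2) continue;
      if (r2 == 0.0) stop("protein atom coincides with a surface atom");
      e += lj(r2, eab, rmin);
    }
  }
  return e;
}

// deterministic golden-spiral (Fibonacci) unit sphere points
static void sphere_points(int n, std::vector<double> &px,
                          std::vector<double> &py, std::vector<double> &pz) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  px.resize(n); py.resize(n); pz.resize(n);
  for (int k = 0; k < n; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n;
    const double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double phi = ga * k;
    px[k] = rho * std::cos(phi);
    py[k] = rho * std::sin(phi);
    pz[k] = z;
  }
}

// exposed-point count for one sphere against an occluder list; occluders
// given as flat arrays of centers and squared expanded radii
static int exposed_points(double cx, double cy, double cz, double R,
                          const std::vector<double> &ox,
                          const std::vector<double> &oy,
                          const std::vector<double> &oz,
                          const std::vector<double> &or2,
                          const std::vector<int> &idx,
                          const std::vector<double> &px,
                          const std::vector<double> &py,
                          const std::vector<double> &pz) {
  const int np = (int)px.size();
  int exposed = 0;
  for (int k = 0; k < np; ++k) {
    const double qx = cx + R * px[k];
    const double qy = cy + R * py[k];
    const double qz = cz + R * pz[k];
    bool buried = false;
    for (size_t m = 0; m < idx.size(); ++m) {
      const int j = idx[m];
      const double dx = qx - ox[j], dy = qy - oy[j], dz = qz - oz[j];
      if (dx * dx + dy * dy + dz * dz < or2[j]) {
        buried = true;
        break;
      }
    }
    if (!buried) ++exposed;
  }
  return exposed;
}

// [[Rcpp::export(name = ".sphere_point_set")]]
NumericMatrix sphere_point_set(int n_points) {
  std::vector<double> px, py, pz;
  sphere_points(n_points, px, py, pz);
  NumericMatrix out(n_points, 3);
  for (int k = 0; k < n_points; ++k) {
    out(k, 0) = px[k];
    out(k, 1) = py[k];
    out(k, 2) = pz[k];
  }
  return out;
}

// [[Rcpp::export(name = ".shrake_rupley")]]
NumericVector shrake_rupley(NumericMatrix coords, NumericVector radii,
                            double probe, int n_points) {
  const int n = coords.nrow();
  std::vector<double> px, py, pz;
  sphere_points(n_points, px, py, pz);
  std::vector<double> x(n), y(n), z(n), R(n), R2(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
    R[i] = radii[i] + probe;
    R2[i] = R[i] * R[i];
  }
  NumericVector area(n);
  std::vector<int> nbr;
  std::vector<std::pair<double, int> > order;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    order.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double lim = R[i] + R[j];
      if (d2 < lim * lim) order.push_back(std::make_pair(d2, j));
    }
    std::sort(order.begin(), order.end());
    for (size_t m = 0; m < order.size(); ++m) nbr.push_back(order[m].second);
    const int expn = exposed_points(x[i], y[i], z[i], R[i], x, y, z, R2, nbr,
                                    px, py, pz);
    area[i] = 4.0 * M_PI * R2[i] * expn / n_points;
  }
  return area;
}

// Intramolecular burial mask of a rigid structure: mask(i, k) is TRUE when
// test point k of atom i lies inside another atom's expanded sphere. For a
// rigid body with body-fixed test points this pattern is pose-invariant,
// so it is computed once from the reference coordinates.
// [[Rcpp::export(name = ".burial_mask")]]
LogicalMatrix burial_mask(NumericMatrix coords, NumericVector radii,
                          double probe, int n_points) {
  const int n = coords.nrow();
  std::vector<double> px, py, pz;
  sphere_points(n_points, px, py, pz);
  std::vector<double> x(n), y(n), z(n), R(n), R2(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
    R[i] = radii[i] + probe;
    R2[i] = R[i] * R[i];
  }
  LogicalMatrix mask(n, n_points);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double lim = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    for (int k = 0; k < n_points; ++k) {
      const double qx = x[i] + R[i] * px[k];
      const double qy = y[i] + R[i] * py[k];
      const double qz = z[i] + R[i] * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double dx = qx - x[j], dy = qy - y[j], dz = qz - z[j];
        if (dx * dx + dy * dy + dz * dz < R2[j]) {
          buried = true;
          break;
        }
      }
      mask(i, k) = buried;
    }
  }
  return mask;
}

// lattice-exposure mask of one basis class of surface atoms: which golden
// spiral points of an interior lattice atom survive its own lattice
static void lattice_exposed_mask(double ax, double ay, double Rs,
                                 double bond,
                                 const std::vector<double> &px,
                                 const std::vector<double> &py,
                                 const std::vector<double> &pz,
                                 std::vector<char> &exposed) {
  std::vector<double> xs, ys;
  lattice_sites_in_disk(ax, ay, 2.0 * Rs + bond, bond, xs, ys);
  const int np = (int)px.size();
  exposed.assign(np, 1);
  for (int k = 0; k < np; ++k) {
    const double qx = ax + Rs * px[k];
    const double qy = ay + Rs * py[k];
    const double qz = Rs * pz[k];
    for (size_t s = 0; s < xs.size(); ++s) {
      const double ddx = xs[s] - ax, ddy = ys[s] - ay;
      if (ddx * ddx + ddy * ddy < 1e-12) continue;  // the atom itself
      const double dx = qx - xs[s], dy = qy - ys[s];
      if (dx * dx + dy * dy + qz * qz < Rs * Rs) {
        exposed[k] = 0;
        break;
      }
    }
  }
}

// Total pose energy against the infinite graphene plane.
//
// VDW: 12-6 lattice sum within the cutoff. Solvation: sigma-weighted
// protein SASA with body-fixed test points (points_lab = pose rotation
// applied to the reference golden spiral; prot_mask is the pose-invariant
// intramolecular burial pattern) plus, for every surface atom the protein
// can occlude, sigma times the change of its area relative to the bare
// lattice value. Referencing surface areas to the bare lattice makes the
// far-field surface contribution exactly zero, so the energy is smooth in
// the pose and equals the infinite-surface limit up to a pose-independent
// constant (the protein's internal SASA term, also exactly constant here).
// [[Rcpp::export(name = ".total_energy_posed")]]
NumericVector total_energy_posed(NumericMatrix ref_coords,
                                 NumericMatrix base_points,
                                 NumericVector centroid,
                                 NumericVector translation,
                                 NumericVector quat,
                                 LogicalMatrix prot_mask, NumericVector eps,
                                 NumericVector rmin_half,
                                 NumericVector radii,
                                 NumericVector sigma_atom, double surf_eps,
                                 double surf_rmin_half, double surf_radius,
                                 double surf_sigma, double bond,
                                 double cutoff, double probe,
                                 double patch_radius) {
  const int nr = ref_coords.nrow();
  const int npt = base_points.nrow();
  // rotation matrix from the unit quaternion (w, x, y, z)
  const double w = quat[0], x = quat[1], y = quat[2], z = quat[3];
  double R[3][3] = {
    {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y)},
    {2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x)},
    {2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)}};
  double shift[3];
  for (int a = 0; a < 3; ++a) {
    shift[a] = centroid[a] + translation[a] -
      (R[a][0] * centroid[0] + R[a][1] * centroid[1] +
       R[a][2] * centroid[2]);
  }
  NumericMatrix coords(nr, 3), points_lab(npt, 3);
  for (int i = 0; i < nr; ++i) {
    for (int a = 0; a < 3; ++a) {
      coords(i, a) = R[a][0] * ref_coords(i, 0) +
        R[a][1] * ref_coords(i, 1) + R[a][2] * ref_coords(i, 2) + shift[a];
    }
  }
  for (int k = 0; k < npt; ++k) {
    for (int a = 0; a < 3; ++a) {
      points_lab(k, a) = R[a][0] * base_points(k, 0) +
        R[a][1] * base_points(k, 1) + R[a][2] * base_points(k, 2);
    }
  }
  const int n = nr;
  const int np = npt;
  const double evdw = vdw_lattice(coords, eps, rmin_half, surf_eps,
                                  surf_rmin_half, bond, cutoff);
  const double Rs = surf_radius + probe;

  bool any_prot_sigma = false;
  for (int i = 0; i < n; ++i) {
    if (sigma_atom[i] != 0.0) {
      any_prot_sigma = true;
      break;
    }
  }
  if (!any_prot_sigma && surf_sigma == 0.0) {
    NumericVector out0(2);
    out0[0] = evdw;
    out0[1] = 0.0;
    return out0;
  }

  std::vector<double> qx(np), qy(np), qz(np);
  for (int k = 0; k < np; ++k) {
    qx[k] = points_lab(k, 0);
    qy[k] = points_lab(k, 1);
    qz[k] = points_lab(k, 2);
  }

  // pose-anchored patch of occludable surface atoms
  double cx = 0.0, cy = 0.0;
  for (int i = 0; i < n; ++i) {
    cx += coords(i, 0);
    cy += coords(i, 1);
  }
  cx /= n; cy /= n;
  std::vector<double> sx, sy;
  lattice_sites_in_disk(cx, cy, patch_radius, bond, sx, sy);
  const int m = (int)sx.size();

  double esolv = 0.0;

  // per-atom count of intramolecularly exposed points (pose-invariant)
  std::vector<int> exp_count(n, 0);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int k = 0; k < np; ++k) {
      if (!prot_mask(i, k)) ++c;
    }
    exp_count[i] = c;
  }
  // protein atoms low enough to interact with surface spheres
  std::vector<int> low;
  for (int i = 0; i < n; ++i) {
    if (std::fabs(coords(i, 2)) < radii[i] + probe + Rs) low.push_back(i);
  }

  // protein atoms: intramolecular burial from the precomputed mask;
  // surface burial tested only for protein-exposed points of atoms low
  // enough to touch the surface's expanded spheres
  for (int i = 0; any_prot_sigma && i < n; ++i) {
    const double Ri = radii[i] + probe;
    const double zi = coords(i, 2);
    int expn = 0;
    if (std::fabs(zi) >= Ri + Rs) {
      expn = exp_count[i];
    } else {
      // surface occluders within reach of this atom
      std::vector<double> nx_, ny_;
      lattice_sites_in_disk(coords(i, 0), coords(i, 1), Ri + Rs, bond, nx_,
                            ny_);
      for (int k = 0; k < np; ++k) {
        if (prot_mask(i, k)) continue;
        const double tx = coords(i, 0) + Ri * qx[k];
        const double ty = coords(i, 1) + Ri * qy[k];
        const double tz = zi + Ri * qz[k];
        bool buried = false;
        if (std::fabs(tz) < Rs) {
          const double h2 = Rs * Rs - tz * tz;
          for (size_t s = 0; s < nx_.size(); ++s) {
            const double dx = tx - nx_[s], dy = ty - ny_[s];
            if (dx * dx + dy * dy < h2) {
              buried = true;
              break;
            }
          }
        }
        if (!buried) ++expn;
      }
    }
    esolv += sigma_atom[i] * 4.0 * M_PI * Ri * Ri * expn / np;
  }

  // surface atoms: deficit = lattice-exposed points newly buried by the
  // protein (reference golden spiral, lab frame)
  if (surf_sigma != 0.0 && m > 0) {
    std::vector<double> gx(np), gy(np), gz(np);
    sphere_points(np, gx, gy, gz);
    std::vector<char> expA, expB;
    lattice_exposed_mask(sx[0], sy[0], Rs, bond, gx, gy, gz, expA);
    // basis class from y mod 1.5 b (A atoms at 0, B atoms at b)
    const double period = 1.5 * bond;
    const double clsA = sy[0] - period * std::floor(sy[0] / period);
    std::vector<double> pR2(n);
    for (int i = 0; i < n; ++i) {
      pR2[i] = (radii[i] + probe) * (radii[i] + probe);
    }
    bool haveB = false;
    for (int k = 0; k < m; ++k) {
      const double cls = sy[k] - period * std::floor(sy[k] / period);
      const bool isA = std::fabs(cls - clsA) < 0.25 * bond ||
                       std::fabs(cls - clsA) > period - 0.25 * bond;
      if (!isA && !haveB) {
        lattice_exposed_mask(sx[k], sy[k], Rs, bond, gx, gy, gz, expB);
        haveB = true;
      }
      // protein neighbors of this surface atom (only low atoms can reach)
      std::vector<int> nbr;
      for (size_t q = 0; q < low.size(); ++q) {
        const int i = low[q];
        const double dx = sx[k] - coords(i, 0), dy = sy[k] - coords(i, 1),
                     dz = coords(i, 2);
        const double lim = Rs + radii[i] + probe;
        if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(i);
      }
      if (nbr.empty()) continue;
      const std::vector<char> &expm = isA ? expA : expB;
      int deficit = 0;
      for (int p = 0; p < np; ++p) {
        if (!expm[p]) continue;
        const double tx = sx[k] + Rs * gx[p];
        const double ty = sy[k] + Rs * gy[p];
        const double tz = Rs * gz[p];
        for (size_t q = 0; q < nbr.size(); ++q) {
          const int i = nbr[q];
          const double dx = tx - coords(i, 0), dy = ty - coords(i, 1),
                       dz = tz - coords(i, 2);
          if (dx * dx + dy * dy + dz * dz < pR2[i]) {
            ++deficit;
            break;
          }
        }
      }
      esolv -= surf_sigma * 4.0 * M_PI * Rs * Rs * deficit / np;
    }
  }

  NumericVector out(2);
  out[0] = evdw;
  out[1] = esolv;
  return out;
}
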