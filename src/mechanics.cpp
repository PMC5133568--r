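#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Overdamped particle core of the epithelial-mechanics module. Cells are
// particles with an interaction radius derived from their volume; pairwise
// attraction-repulsion acts along the interparticle axis and a planarity
// conservation force (standing in for blastocoel turgor pressure) keeps the
// layer monolayered. All loops are O(n) or use a spatial hash, n <= a few
// thousand.

struct PairSet {
  std::vector<int> a, b;      // 0-based indices, a < b
  std::vector<double> r;      // distance
};

static inline long long cell_key(int ix, int iy, int iz) {
  return (static_cast<long long>(ix) * 73856093LL) ^
         (static_cast<long long>(iy) * 19349663LL) ^
         (static_cast<long long>(iz) * 83492791LL);
}

// contact pairs: r_ij < c_max * (R_i + R_j) / 2
static void find_pairs(const NumericMatrix& pos, const NumericVector& R,
                       double c_max, PairSet& out) {
  const int n = pos.nrow();
  out.a.clear(); out.b.clear(); out.r.clear();
  if (n < 2) return;
  double maxR = 0.0;
  for (int i = 0; i < n; ++i) maxR = std::max(maxR, R[i]);
  const double h = std::max(c_max * maxR, 1e-9);

  if (n <= 64) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1),
                     dz = pos(i,2)-pos(j,2);
        const double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < c_max * 0.5 * (R[i] + R[j])) {
          out.a.push_back(i); out.b.push_back(j); out.r.push_back(r);
        }
      }
    }
    return;
  }

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(2 * n);
  std::vector<int> gx(n), gy(n), gz(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (int)std::floor(pos(i,0) / h);
    gy[i] = (int)std::floor(pos(i,1) / h);
    gz[i] = (int)std::floor(pos(i,2) / h);
    grid[cell_key(gx[i], gy[i], gz[i])].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    for (int ox = -1; ox <= 1; ++ox)
    for (int oy = -1; oy <= 1; ++oy)
    for (int oz = -1; oz <= 1; ++oz) {
      auto it = grid.find(cell_key(gx[i]+ox, gy[i]+oy, gz[i]+oz));
      if (it == grid.end()) continue;
      for (int j : it->second) {
        if (j <= i) continue;
        const double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1),
                     dz = pos(i,2)-pos(j,2);
        const double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < c_max * 0.5 * (R[i] + R[j])) {
          out.a.push_back(i); out.b.push_back(j); out.r.push_back(r);
        }
      }
    }
  }
}

// deterministic pseudo-random unit vector for coincident particles
static void hash_dir(int i, int j, double* u) {
  double s1 = std::sin(12.9898 * (i + 1) + 78.233 * (j + 1)) * 43758.5453;
  double s2 = std::sin(26.651 * (i + 1) + 11.713 * (j + 1)) * 19642.3491;
  double s3 = std::sin(53.317 * (i + 1) + 95.177 * (j + 1)) * 31415.9265;
  double x = s1 - std::floor(s1) - 0.5;
  double y = s2 - std::floor(s2) - 0.5;
  double z = s3 - std::floor(s3) - 0.5;
  double nrm = std::sqrt(x*x + y*y + z*z);
  if (nrm < 1e-12) { x = 1; y = 0; z = 0; nrm = 1; }
  u[0] = x / nrm; u[1] = y / nrm; u[2] = z / nrm;
}

struct Params {
  double omega_rep, omega_o, omega_e, k_rig, c_eq, c_max, lambda,
         dt_max, disp_cap;
};

static Params read_params(const List& p) {
  Params q;
  q.omega_rep = as<double>(p["omega_rep"]);
  q.omega_o   = as<double>(p["omega_adh_o"]);
  q.omega_e   = as<double>(p["omega_adh_e"]);
  q.k_rig     = as<double>(p["k_rig"]);
  q.c_eq      = as<double>(p["c_eq"]);
  q.c_max     = as<double>(p["c_max"]);
  q.lambda    = as<double>(p["lambda"]);
  q.dt_max    = as<double>(p["dt_max"]);
  q.disp_cap  = as<double>(p["disp_cap"]);
  return q;
}

// fills F_ar and F_plan (both n x 3, zeroed by caller)
static void accumulate_forces(const NumericMatrix& pos, const NumericVector& R,
                              const IntegerVector& type, const Params& q,
                              const PairSet& pairs,
                              NumericMatrix& F_ar, NumericMatrix& F_plan) {
  const int n = pos.nrow();
  // embryo centroid -> outward normals
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += pos(i,0); cy += pos(i,1); cz += pos(i,2); }
  cx /= n; cy /= n; cz /= n;
  std::vector<double> nx(n), ny(n), nz(n);
  for (int i = 0; i < n; ++i) {
    double vx = pos(i,0)-cx, vy = pos(i,1)-cy, vz = pos(i,2)-cz;
    double nrm = std::sqrt(vx*vx + vy*vy + vz*vz);
    if (nrm < 1e-12) { vx = 0; vy = 0; vz = 1; nrm = 1; }
    nx[i] = vx/nrm; ny[i] = vy/nrm; nz[i] = vz/nrm;
  }

  for (size_t e = 0; e < pairs.a.size(); ++e) {
    const int i = pairs.a[e], j = pairs.b[e];
    double r = pairs.r[e];
    double u[3];
    if (r < 1e-9) {
      hash_dir(i, j, u);
      r = 1e-9;
    } else {
      u[0] = (pos(i,0)-pos(j,0)) / r;
      u[1] = (pos(i,1)-pos(j,1)) / r;
      u[2] = (pos(i,2)-pos(j,2)) / r;
    }
    const double r_eq  = q.c_eq  * 0.5 * (R[i] + R[j]);
    const double r_max = q.c_max * 0.5 * (R[i] + R[j]);
    double mag = 0.0; // along +u = pushes i away from j
    if (r < r_eq) {
      mag = q.omega_rep * (r_eq - r) / r_eq;
    } else if (r < r_max) {
      const double w = (type[i] == type[j]) ? q.omega_o : q.omega_e;
      mag = -w * 4.0 * (r - r_eq) * (r_max - r) /
            ((r_max - r_eq) * (r_max - r_eq));
    }
    for (int d = 0; d < 3; ++d) {
      F_ar(i,d) += mag * u[d];
      F_ar(j,d) -= mag * u[d];
    }
    // planarity conservation: restore the pair into each other's tangent
    // plane along the bisector of their outward normals
    double bx = nx[i]+nx[j], by = ny[i]+ny[j], bz = nz[i]+nz[j];
    const double bn = std::sqrt(bx*bx + by*by + bz*bz);
    if (bn > 1e-9) {
      bx /= bn; by /= bn; bz /= bn;
      const double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1),
                   dz = pos(i,2)-pos(j,2);
      const double d = dx*bx + dy*by + dz*bz;
      const double f = -q.k_rig * d;
      F_plan(i,0) += f*bx; F_plan(i,1) += f*by; F_plan(i,2) += f*bz;
      F_plan(j,0) -= f*bx; F_plan(j,1) -= f*by; F_plan(j,2) -= f*bz;
    }
  }
}

// [[Rcpp::export(name = ".mech_contacts_cpp")]]
List mech_contacts_cpp(NumericMatrix pos, NumericVector radius, double c_max) {
  PairSet pairs;
  find_pairs(pos, radius, c_max, pairs);
  const int m = pairs.a.size();
  IntegerVector ia(m), jb(m);
  NumericVector rr(m);
  for (int e = 0; e < m; ++e) {
    ia[e] = pairs.a[e] + 1; jb[e] = pairs.b[e] + 1; rr[e] = pairs.r[e];
  }
  return List::create(_["i"] = ia, _["j"] = jb, _["r"] = rr);
}

// [[Rcpp::export(name = ".mech_forces_cpp")]]
List mech_forces_cpp(NumericMatrix pos, NumericVector radius,
                     IntegerVector type, List params) {
  const Params q = read_params(params);
  PairSet pairs;
  find_pairs(pos, radius, q.c_max, pairs);
  const int n = pos.nrow();
  NumericMatrix F_ar(n, 3), F_plan(n, 3);
  accumulate_forces(pos, radius, type, q, pairs, F_ar, F_plan);
  const int m = pairs.a.size();
  IntegerVector ia(m), jb(m);
  NumericVector rr(m);
  for (int e = 0; e < m; ++e) {
    ia[e] = pairs.a[e] + 1; jb[e] = pairs.b[e] + 1; rr[e] = pairs.r[e];
  }
  return List::create(_["F_ar"] = F_ar, _["F_plan"] = F_plan,
                      _["i"] = ia, _["j"] = jb, _["r"] = rr);
}

// Relax the configuration by overdamped steps x += F/lambda * dt with the
// step clamped so no particle moves more than disp_cap * min r_eq per step.
// Stops after max_steps or when the largest displacement of a step falls
// below tol (um).
// [[Rcpp::export(name = ".mech_integrate_cpp")]]
List mech_integrate_cpp(NumericMatrix pos_in, NumericVector radius,
                        IntegerVector type, List params,
                        int max_steps, double tol) {
  const Params q = read_params(params);
  NumericMatrix pos = clone(pos_in);
  const int n = pos.nrow();
  double minR = R_PosInf;
  for (int i = 0; i < n; ++i) minR = std::min(minR, (double)radius[i]);
  const double req_min = q.c_eq * minR;
  const double cap = q.disp_cap * req_min;

  PairSet pairs;
  NumericMatrix F_ar(n, 3), F_plan(n, 3);
  std::vector<double> Fprev(3 * n, 0.0);
  int steps = 0;
  bool converged = false;
  double last_disp = NA_REAL;
  double dt = q.dt_max;

  for (steps = 0; steps < max_steps; ++steps) {
    find_pairs(pos, radius, q.c_max, pairs);
    std::fill(F_ar.begin(), F_ar.end(), 0.0);
    std::fill(F_plan.begin(), F_plan.end(), 0.0);
    accumulate_forces(pos, radius, type, q, pairs, F_ar, F_plan);

    double maxF = 0.0, dotFF = 0.0;
    for (int i = 0; i < n; ++i) {
      const double fx = F_ar(i,0)+F_plan(i,0), fy = F_ar(i,1)+F_plan(i,1),
                   fz = F_ar(i,2)+F_plan(i,2);
      maxF = std::max(maxF, std::sqrt(fx*fx + fy*fy + fz*fz));
      dotFF += fx*Fprev[3*i] + fy*Fprev[3*i+1] + fz*Fprev[3*i+2];
      Fprev[3*i] = fx; Fprev[3*i+1] = fy; Fprev[3*i+2] = fz;
    }
    if (maxF < 1e-14) { converged = true; last_disp = 0.0; break; }
    // adaptive step control against explicit-Euler overshoot: shrink the
    // step when the force field reverses (oscillation), grow it gently
    // while descending
    if (steps > 0) {
      if (dotFF < 0.0) dt *= 0.5; else dt = std::min(dt * 1.1, q.dt_max);
      if (dt < 1e-6 * q.dt_max) dt = 1e-6 * q.dt_max;
    }
    double dt_eff = dt;
    if (maxF / q.lambda * dt_eff > cap) dt_eff = cap * q.lambda / maxF;
    for (int i = 0; i < n; ++i) {
      pos(i,0) += (F_ar(i,0)+F_plan(i,0)) / q.lambda * dt_eff;
      pos(i,1) += (F_ar(i,1)+F_plan(i,1)) / q.lambda * dt_eff;
      pos(i,2) += (F_ar(i,2)+F_plan(i,2)) / q.lambda * dt_eff;
      if (!std::isfinite(pos(i,0)) || !std::isfinite(pos(i,1)) ||
          !std::isfinite(pos(i,2))) {
        stop("non-finite particle position during integration (cell %d)", i + 1);
      }
    }
    last_disp = maxF / q.lambda * dt_eff;
    if (last_disp < tol) { converged = true; ++steps; break; }
  }
  return List::create(_["pos"] = pos, _["steps"] = steps,
                      _["converged"] = converged, _["last_disp"] = last_disp);
}
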