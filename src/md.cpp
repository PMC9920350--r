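// Continuous-space molecular dynamics for the binary SALR-type mixture.
//
// Pair potentials (energies in epsilon, lengths in the particle diameter a):
//   V11(r) = 6[ r^-12 - r^-6 + 0.3 e^{-r/2}/r ]
//   V22(r) = V11(r)/q^2
//   V12(r) = 6[ r^-12 + r^-6 - 0.3 e^{-r/2}/r ]/q
// truncated at r_cut = 6.75 (optionally shifted to zero at the cutoff).
//
// Geometry: rectangular box, periodic in x and y, confining walls at z = 0
// and z = Lz.  Wall potentials:
//   repulsive  V_rep(z)  = 2/(z - zw)^12          (zw = 0 or Lz)
//   attractive V_attr(z) = 4[ z^-12 - z^-6 ]      (wall at z = 0)
//
// Integrator: velocity Verlet with cell-list force evaluation; temperature
// imposed by periodic velocity scaling (uniform or in z-zones).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
#include <map>
using namespace Rcpp;

static const double RCUT_DEFAULT = 6.75;

struct PairParams {
  double q, rcut, rcut2;
  bool shifted;
  double pref[3];   // 0: 11, 1: 22, 2: 12
  double shift[3];
  static double bracket(double r, int sgn) {
    double inv = 1.0 / r;
    double i6 = inv * inv * inv; i6 *= i6;
    return i6 * i6 + sgn * (-i6 + 0.3 * std::exp(-0.5 * r) * inv);
  }
  static double dbracket(double r, int sgn) {
    double inv = 1.0 / r;
    double i6 = inv * inv * inv; i6 *= i6;
    double i7 = i6 * inv, i13 = i6 * i6 * inv;
    return -12.0 * i13 +
           sgn * (6.0 * i7 + 0.3 * std::exp(-0.5 * r) * (-0.5 * inv - inv * inv));
  }
  void init(double q_, double rcut_, bool shifted_) {
    q = q_; rcut = rcut_; rcut2 = rcut_ * rcut_; shifted = shifted_;
    pref[0] = 6.0; pref[1] = 6.0 / (q * q); pref[2] = 6.0 / q;
    for (int t = 0; t < 3; ++t)
      shift[t] = shifted ? pref[t] * bracket(rcut, t == 2 ? -1 : 1) : 0.0;
  }
  inline int type(int si, int sj) const {
    return si == sj ? (si == 1 ? 0 : 1) : 2;
  }
  inline double energy(double r, int t) const {
    if (r >= rcut) return 0.0;
    return pref[t] * bracket(r, t == 2 ? -1 : 1) - shift[t];
  }
  inline double dVdr(double r, int t) const {
    if (r >= rcut) return 0.0;
    return pref[t] * dbracket(r, t == 2 ? -1 : 1);
  }
};

// [[Rcpp::export(name = ".pair_potential_cpp")]]
NumericVector pair_potential_cpp(NumericVector r, int species_i, int species_j,
                                 double q, double rcut, bool shifted) {
  PairParams pp; pp.init(q, rcut, shifted);
  int t = pp.type(species_i, species_j);
  NumericVector out(r.size());
  for (int k = 0; k < r.size(); ++k) {
    if (r[k] <= 0) stop("pair distance must be positive");
    out[k] = pp.energy(r[k], t);
  }
  return out;
}

// radial force F(r) = -dV/dr (positive = repulsive)
// [[Rcpp::export(name = ".pair_force_cpp")]]
NumericVector pair_force_cpp(NumericVector r, int species_i, int species_j,
                             double q, double rcut, bool shifted) {
  PairParams pp; pp.init(q, rcut, shifted);
  int t = pp.type(species_i, species_j);
  NumericVector out(r.size());
  for (int k = 0; k < r.size(); ++k) {
    if (r[k] <= 0) stop("pair distance must be positive");
    out[k] = -pp.dVdr(r[k], t);
  }
  return out;
}

// wall energies/forces; z measured from the z = 0 plane
static inline double wall_rep_e(double d) {
  double i3 = 1.0 / (d * d * d); double i12 = i3 * i3; i12 *= i12;
  return 2.0 * i12;
}
static inline double wall_rep_f(double d) {  // -dV/dd
  double i = 1.0 / d; double i3 = i * i * i; double i13 = i3 * i3; i13 *= i13; i13 *= i;
  return 24.0 * i13;
}
static inline double wall_attr_e(double z) {
  double i3 = 1.0 / (z * z * z); double i6 = i3 * i3;
  return 4.0 * (i6 * i6 - i6);
}
static inline double wall_attr_f(double z) {  // -dV/dz
  double i = 1.0 / z; double i3 = i * i * i; double i6 = i3 * i3;
  double i7 = i6 * i, i13 = i6 * i6 * i;
  return 48.0 * i13 - 24.0 * i7;
}

// [[Rcpp::export(name = ".wall_terms_cpp")]]
NumericVector wall_terms_cpp(double z, int species, int z0_type, double Lz) {
  // returns c(energy, force_z) from both walls
  if (z <= 0 || z >= Lz) stop("particle outside the slab (0 < z < Lz required)");
  double e = 0, f = 0;
  bool attracted = (z0_type == 2) || (z0_type == 1 && species == 1);
  if (attracted) { e += wall_attr_e(z); f += wall_attr_f(z); }
  else           { e += wall_rep_e(z);  f += wall_rep_f(z); }
  double d = Lz - z;
  e += wall_rep_e(d); f -= wall_rep_f(d);
  return NumericVector::create(e, f);
}

struct CellList {
  int nx, ny, nz;
  double bx, by, bz, Lx, Ly, Lz;
  std::vector<std::vector<int>> bins;
  std::vector<std::vector<int>> nbr;  // neighbour bins with id >= own
  void setup(double Lx_, double Ly_, double Lz_, double rcut) {
    Lx = Lx_; Ly = Ly_; Lz = Lz_;
    nx = std::max(1, (int)(Lx / rcut));
    ny = std::max(1, (int)(Ly / rcut));
    nz = std::max(1, (int)(Lz / rcut));
    bx = Lx / nx; by = Ly / ny; bz = Lz / nz;
    int nb = nx * ny * nz;
    bins.assign(nb, {});
    nbr.assign(nb, {});
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int b = (z * ny + y) * nx + x;
          std::vector<int> u;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;  // no z periodicity
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int xx = ((x + dx) % nx + nx) % nx;
                int yy = ((y + dy) % ny + ny) % ny;
                int c = (zz * ny + yy) * nx + xx;
                if (c >= b) u.push_back(c);
              }
          }
          std::sort(u.begin(), u.end());
          u.erase(std::unique(u.begin(), u.end()), u.end());
          nbr[b] = u;
        }
  }
  inline int bin_of(double x, double y, double z) const {
    int ix = (int)(x / bx); if (ix >= nx) ix = nx - 1; if (ix < 0) ix = 0;
    int iy = (int)(y / by); if (iy >= ny) iy = ny - 1; if (iy < 0) iy = 0;
    int iz = (int)(z / bz); if (iz >= nz) iz = nz - 1; if (iz < 0) iz = 0;
    return (iz * ny + iy) * nx + ix;
  }
  void fill(const std::vector<double>& x, const std::vector<double>& y,
            const std::vector<double>& z) {
    for (auto& b : bins) b.clear();
    for (size_t i = 0; i < x.size(); ++i)
      bins[bin_of(x[i], y[i], z[i])].push_back((int)i);
  }
};

// [[Rcpp::export(name = ".md_run_cpp")]]
List md_run_cpp(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species,
                double Lx, double Ly, double Lz, double q, int z0_type,
                double dt, int nsteps, int rescale_interval, double T_target,
                Nullable<NumericMatrix> zones_, double rcut, bool shifted,
                int record_interval) {
  int N = pos0.nrow();
  if (Lx < 2 * rcut || Ly < 2 * rcut)
    stop("box too small for minimum image at this cutoff (need Lx, Ly >= 2*rcut)");
  PairParams pp; pp.init(q, rcut, shifted);
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N);
  std::vector<double> fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
    if (z[i] <= 0 || z[i] >= Lz) stop("initial particle outside the slab");
  }
  NumericMatrix zones = zones_.isNotNull()
      ? NumericMatrix(zones_)
      : NumericMatrix(0, 3);
  CellList cl; cl.setup(Lx, Ly, Lz, rcut);

  double pe = 0;
  auto forces = [&](bool with_pe) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pe = 0;
    cl.fill(x, y, z);
    int nb = (int)cl.bins.size();
    for (int b = 0; b < nb; ++b) {
      for (int c : cl.nbr[b]) {
        const std::vector<int>& A = cl.bins[b];
        const std::vector<int>& B = cl.bins[c];
        for (size_t ai = 0; ai < A.size(); ++ai) {
          int i = A[ai];
          size_t start = (b == c) ? ai + 1 : 0;
          for (size_t bi = start; bi < B.size(); ++bi) {
            int j = B[bi];
            double dx = x[i] - x[j];
            double dy = y[i] - y[j];
            double dz = z[i] - z[j];
            dx -= Lx * std::round(dx / Lx);
            dy -= Ly * std::round(dy / Ly);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= pp.rcut2) continue;
            if (r2 < 0.25)
              stop("pair overlap (r < 0.5): configuration or timestep unstable");
            double r = std::sqrt(r2);
            int t = pp.type(species[i], species[j]);
            double fr = -pp.dVdr(r, t) / r;
            fx[i] += fr * dx; fx[j] -= fr * dx;
            fy[i] += fr * dy; fy[j] -= fr * dy;
            fz[i] += fr * dz; fz[j] -= fr * dz;
            if (with_pe) pe += pp.energy(r, t);
          }
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      bool attracted = (z0_type == 2) || (z0_type == 1 && species[i] == 1);
      if (attracted) { fz[i] += wall_attr_f(z[i]); if (with_pe) pe += wall_attr_e(z[i]); }
      else           { fz[i] += wall_rep_f(z[i]);  if (with_pe) pe += wall_rep_e(z[i]); }
      double d = Lz - z[i];
      fz[i] -= wall_rep_f(d);
      if (with_pe) pe += wall_rep_e(d);
    }
  };

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < N; ++i)
      ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    return 0.5 * ke;
  };

  auto rescale = [&]() {
    if (zones.nrow() > 0) {
      for (int r = 0; r < zones.nrow(); ++r) {
        double zlo = zones(r, 0), zhi = zones(r, 1), Tt = zones(r, 2);
        double ke = 0; int n = 0;
        for (int i = 0; i < N; ++i)
          if (z[i] >= zlo && z[i] < zhi) {
            ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
            ++n;
          }
        if (n == 0 || ke <= 0) continue;
        double f = std::sqrt(3.0 * n * Tt / ke);
        for (int i = 0; i < N; ++i)
          if (z[i] >= zlo && z[i] < zhi) { vx[i] *= f; vy[i] *= f; vz[i] *= f; }
      }
    } else if (R_finite(T_target)) {
      double ke = 2.0 * kinetic();
      if (ke > 0) {
        double f = std::sqrt(3.0 * N * T_target / ke);
        for (int i = 0; i < N; ++i) { vx[i] *= f; vy[i] *= f; vz[i] *= f; }
      }
    }
  };

  std::vector<double> rs_step, rs_Tkin, rs_pe, rs_etot, rs_px, rs_py;
  forces(true);
  bool thermo = R_finite(T_target) || zones.nrow() > 0;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
      x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
      if (z[i] <= 0 || z[i] >= Lz)
        stop("particle escaped the slab: reduce dt or check wall parameters");
    }
    bool rec = record_interval > 0 && step % record_interval == 0;
    forces(true);
    for (int i = 0; i < N; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
    }
    if (thermo && rescale_interval > 0 && step % rescale_interval == 0) rescale();
    if (rec) {
      double ke = kinetic();
      double px = 0, py = 0;
      for (int i = 0; i < N; ++i) { px += vx[i]; py += vy[i]; }
      rs_step.push_back(step);
      rs_Tkin.push_back(2.0 * ke / (3.0 * N));
      rs_pe.push_back(pe);
      rs_etot.push_back(pe + ke);
      rs_px.push_back(px);
      rs_py.push_back(py);
    }
    if (step % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix pos(N, 3), vel(N, 3);
  for (int i = 0; i < N; ++i) {
    pos(i, 0) = x[i]; pos(i, 1) = y[i]; pos(i, 2) = z[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i];
  }
  return List::create(
      _["positions"] = pos, _["velocities"] = vel,
      _["series"] = DataFrame::create(
          _["step"] = rs_step, _["T_kin"] = rs_Tkin, _["PE"] = rs_pe,
          _["E_total"] = rs_etot, _["Px"] = rs_px, _["Py"] = rs_py),
      _["potential_energy"] = pe);
}

// total potential energy of a static configuration (for tests of cell-list
// independence and for run bookkeeping)
// [[Rcpp::export(name = ".md_potential_energy")]]
double md_potential_energy(NumericMatrix pos, IntegerVector species,
                           double Lx, double Ly, double Lz, double q,
                           int z0_type, double rcut, bool shifted,
                           double bin_scale) {
  int N = pos.nrow();
  PairParams pp; pp.init(q, rcut, shifted);
  double pe = 0;
  // all pairs with minimum image in x, y (reference implementation,
  // independent of any cell decomposition when bin_scale <= 0)
  (void)bin_scale;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= Lx * std::round(dx / Lx);
      dy -= Ly * std::round(dy / Ly);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rcut) pe += pp.energy(r, pp.type(species[i], species[j]));
    }
    double z = pos(i, 2);
    bool attracted = (z0_type == 2) || (z0_type == 1 && species[i] == 1);
    pe += attracted ? wall_attr_e(z) : wall_rep_e(z);
    pe += wall_rep_e(Lz - z);
  }
  return pe;
}

// connected components of particles within a distance cutoff (periodic x, y)
// [[Rcpp::export(name = ".continuous_components")]]
IntegerVector continuous_components(NumericMatrix pos, double Lx, double Ly,
                                    double cutoff) {
  int N = pos.nrow();
  std::vector<int> parent(N);
  for (int i = 0; i < N; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };
  double c2 = cutoff * cutoff;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= Lx * std::round(dx / Lx);
      dy -= Ly * std::round(dy / Ly);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        int a = find(i), b = find(j);
        if (a != b) parent[a] = b;
      }
    }
  IntegerVector comp(N);
  std::map<int, int> relabel;
  for (int i = 0; i < N; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { comp[i] = (int)relabel.size() + 1; relabel[r] = comp[i]; }
    else comp[i] = it->second;
  }
  return comp;
}
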