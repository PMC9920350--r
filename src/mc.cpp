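// Grand-canonical and canonical Metropolis Monte Carlo on the lattice
// mixture.  One MC step = one attempted move per lattice site (grand
// canonical) or per particle (canonical).
//
// Insertion/removal acceptance at temperature T*:
//   p(ins, species i) = min(1, exp[(u_i + mu_i)/T*])
//   p(rem, species i) = min(1, exp[-(u_i + mu_i)/T*])
// with u_1 = -u_2 = Delta1 - J*Delta2 evaluated from the local fields, i.e.
// u_i is minus the insertion energy change of species i.  Acceptance factors
// are tabulated over the 13 x 13 possible (Delta1, Delta2) integer fields.
//
// Energies are tracked as exact integers (e0, e1) with E = e0 + e1*J and
// re-validated from scratch every 10^4 attempted moves; any mismatch aborts.
//
// RNG: a xoshiro256++ stream seeded from R's RNG, so set.seed() in R fully
// determines a run.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const int DX1[6] = {1, -1, 0, 0, 1, -1};
static const int DY1[6] = {0, 0, 1, -1, -1, 1};
static inline int wrap(int v, int L) { return ((v % L) + L) % L; }
static inline int sid(int i, int j, int L) { return wrap(i, L) + wrap(j, L) * L; }

struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_R() {
    for (int k = 0; k < 4; ++k) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[k] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (k + 1));
    }
    for (int k = 0; k < 16; ++k) next();  // warm up
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(u01() * n); }
};

// acceptance factor, the quantity tabulated in the run kernels; exported for
// the detailed-balance unit tests
// [[Rcpp::export(name = ".gcmc_acceptance")]]
double gcmc_acceptance(double J, double T, double mu1, double mu2,
                       int d1, int d2, int species, std::string move) {
  double u = (species == 1 ? 1.0 : -1.0) * (d1 - J * d2);
  double mu = species == 1 ? mu1 : mu2;
  double x = (u + mu) / T;
  if (move == "removal") x = -x;
  else if (move != "insertion") stop("move must be 'insertion' or 'removal'");
  return x >= 0 ? 1.0 : std::exp(x);
}

struct AccTables {
  // [species 0/1][move ins=0/rem=1][(d1+6)*13 + (d2+6)]
  double t[2][2][169];
  void build(double J, double T, double mu1, double mu2) {
    for (int sp = 0; sp < 2; ++sp)
      for (int d1 = -6; d1 <= 6; ++d1)
        for (int d2 = -6; d2 <= 6; ++d2) {
          double u = (sp == 0 ? 1.0 : -1.0) * (d1 - J * d2);
          double mu = sp == 0 ? mu1 : mu2;
          int ix = (d1 + 6) * 13 + (d2 + 6);
          double xi = (u + mu) / T, xr = -xi;
          t[sp][0][ix] = xi >= 0 ? 1.0 : std::exp(xi);
          t[sp][1][ix] = xr >= 0 ? 1.0 : std::exp(xr);
        }
  }
};

static void check_energy(const std::vector<int>& S, int L, long e0, long e1) {
  long f0 = 0, f1 = 0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = S[i + j * L];
      if (!s) continue;
      for (int d = 0; d < 6; ++d) {
        int v1 = S[sid(i + DX1[d], j + DY1[d], L)];
        if (v1) f0 -= s * v1;
        int v3 = S[sid(i + 2 * DX1[d], j + 2 * DY1[d], L)];
        if (v3) f1 += s * v3;
      }
    }
  if (f0 / 2 != e0 || f1 / 2 != e1)
    stop("internal error: incremental energy bookkeeping diverged from recomputation");
}

// Run a full annealing schedule of GCMC.  Returns the final configuration,
// a time series sampled every record_interval steps, and snapshots stored
// every snapshot_interval production steps of the final temperature.
// The local fields (Delta1, Delta2) of every site are maintained
// incrementally and, together with the energy, re-validated from scratch
// every validate_interval attempted moves.
// [[Rcpp::export(name = ".run_gcmc")]]
List run_gcmc(IntegerVector S0, int L, double J, double mu1, double mu2,
              NumericVector temps, int equil_steps, int prod_steps,
              int record_interval, int snapshot_interval, int max_snapshots,
              double validate_interval) {
  int N = L * L;
  std::vector<int> S(S0.begin(), S0.end());
  std::vector<int> nb(N * 12);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = i + j * L;
      for (int d = 0; d < 6; ++d) {
        nb[s * 12 + d] = sid(i + DX1[d], j + DY1[d], L);
        nb[s * 12 + 6 + d] = sid(i + 2 * DX1[d], j + 2 * DY1[d], L);
      }
    }
  // incremental fields per site
  std::vector<signed char> D1(N), D2(N);
  auto rebuild_fields = [&]() {
    for (int s = 0; s < N; ++s) {
      int d1 = 0, d2 = 0;
      for (int d = 0; d < 6; ++d) {
        d1 += S[nb[s * 12 + d]];
        d2 += S[nb[s * 12 + 6 + d]];
      }
      D1[s] = (signed char)d1; D2[s] = (signed char)d2;
    }
  };
  rebuild_fields();
  auto check_fields = [&]() {
    for (int s = 0; s < N; ++s) {
      int d1 = 0, d2 = 0;
      for (int d = 0; d < 6; ++d) {
        d1 += S[nb[s * 12 + d]];
        d2 += S[nb[s * 12 + 6 + d]];
      }
      if (d1 != D1[s] || d2 != D2[s])
        stop("internal error: incremental local fields diverged");
    }
  };
  long e0 = 0, e1 = 0;
  {
    long f0 = 0, f1 = 0;
    for (int s = 0; s < N; ++s) {
      int v = S[s];
      if (!v) continue;
      f0 -= v * D1[s]; f1 += v * D2[s];
    }
    e0 = f0 / 2; e1 = f1 / 2;
  }
  long n1 = 0, n2 = 0;
  for (int s = 0; s < N; ++s) { if (S[s] == 1) ++n1; else if (S[s] == -1) ++n2; }

  GetRNGstate();
  Xoshiro rng; rng.seed_from_R();
  PutRNGstate();

  int ntemp = temps.size();
  std::vector<double> rec_step, rec_T, rec_N1, rec_N2, rec_E;
  List snapshots;
  AccTables acc;
  long moves = 0;
  long next_check = (long)validate_interval;
  if (next_check < 1) next_check = 1;

  for (int it = 0; it < ntemp; ++it) {
    double T = temps[it];
    if (T <= 0) stop("temperatures must be positive");
    acc.build(J, T, mu1, mu2);
    int total = equil_steps + prod_steps;
    for (int step = 0; step < total; ++step) {
      for (int a = 0; a < N; ++a) {
        int site = rng.below(N);
        int d1 = D1[site], d2 = D2[site];
        int ix = (d1 + 6) * 13 + (d2 + 6);
        int v = S[site];
        int ds = 0;
        if (v == 0) {
          int sp = (int)(rng.next() & 1);  // 0 -> species 1, 1 -> species 2
          double p = acc.t[sp][0][ix];
          if (p >= 1.0 || rng.u01() < p) {
            ds = sp == 0 ? 1 : -1;
            S[site] = ds;
            e0 -= ds * d1; e1 += ds * d2;
            if (sp == 0) ++n1; else ++n2;
          }
        } else {
          int sp = v == 1 ? 0 : 1;
          double p = acc.t[sp][1][ix];
          if (p >= 1.0 || rng.u01() < p) {
            ds = -v;
            S[site] = 0;
            e0 += v * d1; e1 -= v * d2;
            if (v == 1) --n1; else --n2;
          }
        }
        if (ds != 0) {
          const int* nbs = &nb[site * 12];
          for (int d = 0; d < 6; ++d) D1[nbs[d]] += ds;
          for (int d = 0; d < 6; ++d) D2[nbs[6 + d]] += ds;
        }
        if (++moves >= next_check) {
          check_energy(S, L, e0, e1);
          check_fields();
          next_check += (long)validate_interval;
        }
      }
      if ((step + 1) % record_interval == 0) {
        rec_step.push_back(step + 1);
        rec_T.push_back(T);
        rec_N1.push_back((double)n1);
        rec_N2.push_back((double)n2);
        rec_E.push_back(e0 + e1 * J);
      }
      if (it == ntemp - 1 && step >= equil_steps &&
          (step - equil_steps + 1) % snapshot_interval == 0 &&
          snapshots.size() < max_snapshots) {
        snapshots.push_back(IntegerVector(S.begin(), S.end()));
      }
    }
    Rcpp::checkUserInterrupt();
  }
  check_energy(S, L, e0, e1);
  return List::create(
      _["S"] = IntegerVector(S.begin(), S.end()),
      _["series"] = DataFrame::create(
          _["step"] = rec_step, _["T"] = rec_T, _["N1"] = rec_N1,
          _["N2"] = rec_N2, _["E"] = rec_E),
      _["snapshots"] = snapshots,
      _["energy_parts"] = IntegerVector::create((int)e0, (int)e1));
}

// Canonical (fixed N1, N2) annealing with single-particle displacement moves
// to empty first-shell sites; Metropolis acceptance min(1, exp(-dE/T*)).
// [[Rcpp::export(name = ".run_canonical")]]
List run_canonical(IntegerVector S0, int L, double J, NumericVector temps,
                   int equil_steps, int prod_steps, int record_interval) {
  int N = L * L;
  std::vector<int> S(S0.begin(), S0.end());
  std::vector<int> part;            // site of each particle
  std::vector<int> slot(N, -1);     // particle index at a site
  for (int s = 0; s < N; ++s)
    if (S[s]) { slot[s] = (int)part.size(); part.push_back(s); }
  int np = (int)part.size();
  if (np == 0) stop("canonical run needs at least one particle");
  if (np >= N) stop("canonical run needs at least one empty site");

  std::vector<int> nb(N * 12);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = i + j * L;
      for (int d = 0; d < 6; ++d) {
        nb[s * 12 + d] = sid(i + DX1[d], j + DY1[d], L);
        nb[s * 12 + 6 + d] = sid(i + 2 * DX1[d], j + 2 * DY1[d], L);
      }
    }
  long e0 = 0, e1 = 0;
  for (int s = 0; s < N; ++s) {
    int v = S[s]; if (!v) continue;
    for (int d = 0; d < 6; ++d) {
      int v1 = S[nb[s * 12 + d]]; if (v1) e0 -= v * v1;
      int v3 = S[nb[s * 12 + 6 + d]]; if (v3) e1 += v * v3;
    }
  }
  e0 /= 2; e1 /= 2;

  GetRNGstate();
  Xoshiro rng; rng.seed_from_R();
  PutRNGstate();

  // dE = de0 + J*de1 with de0, de1 in [-13, 13]
  double accT[27 * 27];
  std::vector<double> rec_step, rec_T, rec_E;
  long moves = 0, next_check = 10000;
  int ntemp = temps.size();
  for (int it = 0; it < ntemp; ++it) {
    double T = temps[it];
    if (T <= 0) stop("temperatures must be positive");
    for (int a = -13; a <= 13; ++a)
      for (int b = -13; b <= 13; ++b) {
        double dE = a + J * b;
        accT[(a + 13) * 27 + (b + 13)] = dE <= 0 ? 1.0 : std::exp(-dE / T);
      }
    int total = equil_steps + prod_steps;
    for (int step = 0; step < total; ++step) {
      for (int a = 0; a < np; ++a) {
        int pi = rng.below(np);
        int from = part[pi];
        int to = nb[from * 12 + rng.below(6)];
        if (S[to] != 0) continue;
        int v = S[from];
        // fields at the old site (particle's own site excluded automatically)
        int d1f = 0, d2f = 0;
        for (int d = 0; d < 6; ++d) d1f += S[nb[from * 12 + d]];
        for (int d = 0; d < 6; ++d) d2f += S[nb[from * 12 + 6 + d]];
        S[from] = 0;
        int d1t = 0, d2t = 0;
        for (int d = 0; d < 6; ++d) d1t += S[nb[to * 12 + d]];
        for (int d = 0; d < 6; ++d) d2t += S[nb[to * 12 + 6 + d]];
        int de0 = v * (d1f - d1t);   // -(new NN energy) + (old NN energy)
        int de1 = v * (d2t - d2f);
        double p = accT[(de0 + 13) * 27 + (de1 + 13)];
        if (p >= 1.0 || rng.u01() < p) {
          S[to] = v;
          part[pi] = to;
          slot[to] = pi; slot[from] = -1;
          e0 += de0; e1 += de1;
        } else {
          S[from] = v;
        }
        if (++moves >= next_check) {
          check_energy(S, L, e0, e1);
          next_check += 10000;
        }
      }
      if ((step + 1) % record_interval == 0) {
        rec_step.push_back(step + 1);
        rec_T.push_back(T);
        rec_E.push_back(e0 + e1 * J);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  check_energy(S, L, e0, e1);
  return List::create(
      _["S"] = IntegerVector(S.begin(), S.end()),
      _["series"] = DataFrame::create(_["step"] = rec_step, _["T"] = rec_T,
                                      _["E"] = rec_E),
      _["energy_parts"] = IntegerVector::create((int)e0, (int)e1));
}
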