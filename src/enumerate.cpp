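// Brute-force enumeration of periodic patterns: every sublattice of the
// triangular lattice with cell area n <= max_cell_sites (one Hermite-normal-
// form basis [[a,0],[c,b]] per sublattice, ab = n, 0 <= c < a), every spin-1
// occupancy of the cell (3^n of them).  Each pattern is reduced to the
// J/mu-independent tuple (e0, e1, n1, n2, area) with cell energy
// E = e0 + e1*J, so a single enumeration serves any (J, mu1, mu2).
//
// Per-site grand potential of a tuple: h = (e0 + e1*J - n1*mu1 - n2*mu2)/area.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int DX1[6] = {1, -1, 0, 0, 1, -1};
static const int DY1[6] = {0, 0, 1, -1, -1, 1};

static inline int cell_index(int x, int y, int a, int b, int cshift) {
  int j = ((y % b) + b) % b;
  int k = (y - j) / b;
  int xp = x - k * cshift;
  int i = ((xp % a) + a) % a;
  return i + j * a;
}

// [[Rcpp::export(name = ".enumerate_cell_tuples")]]
IntegerMatrix enumerate_cell_tuples(int max_cell_sites) {
  if (max_cell_sites < 1 || max_cell_sites > 12)
    stop("cell budget exceeded: max_cell_sites must be between 1 and 12");
  std::unordered_set<uint64_t> seen;
  std::vector<int> rows;  // flat (e0, e1, n1, n2, area)
  for (int n = 1; n <= max_cell_sites; ++n) {
    long nconf = 1;
    for (int k = 0; k < n; ++k) nconf *= 3;
    for (int a = 1; a <= n; ++a) {
      if (n % a) continue;
      int b = n / a;
      for (int cs = 0; cs < a; ++cs) {
        // neighbour index tables for this cell
        std::vector<int> nb1(n * 6), nb3(n * 6);
        for (int j = 0; j < b; ++j)
          for (int i = 0; i < a; ++i) {
            int s = i + j * a;
            for (int d = 0; d < 6; ++d) {
              nb1[s * 6 + d] = cell_index(i + DX1[d], j + DY1[d], a, b, cs);
              nb3[s * 6 + d] = cell_index(i + 2 * DX1[d], j + 2 * DY1[d], a, b, cs);
            }
          }
        std::vector<int> S(n);
        for (long code = 0; code < nconf; ++code) {
          long x = code;
          int n1 = 0, n2 = 0;
          for (int k = 0; k < n; ++k) {
            int v = (int)(x % 3); x /= 3;
            S[k] = v == 2 ? -1 : v;  // 0, +1, -1
            if (S[k] == 1) ++n1; else if (S[k] == -1) ++n2;
          }
          if (n1 + n2 == 0) continue;
          int e0 = 0, e1 = 0;
          for (int s = 0; s < n; ++s) {
            int v = S[s];
            if (!v) continue;
            for (int d = 0; d < 6; ++d) {
              int v1 = S[nb1[s * 6 + d]];
              if (v1) e0 -= v * v1;
              int v3 = S[nb3[s * 6 + d]];
              if (v3) e1 += v * v3;
            }
          }
          e0 /= 2; e1 /= 2;
          uint64_t key = ((uint64_t)(e0 + 128)) |
                         ((uint64_t)(e1 + 128) << 9) |
                         ((uint64_t)n1 << 18) | ((uint64_t)n2 << 24) |
                         ((uint64_t)n << 30);
          if (seen.insert(key).second) {
            rows.push_back(e0); rows.push_back(e1);
            rows.push_back(n1); rows.push_back(n2); rows.push_back(n);
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  int m = (int)(rows.size() / 5);
  IntegerMatrix out(m, 5);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 5; ++c) out(r, c) = rows[r * 5 + c];
  colnames(out) = CharacterVector::create("e0", "e1", "n1", "n2", "area");
  return out;
}

// Minimum per-site grand potential over enumerated tuples at each
// (mu1[k], mu2[k]); the empty pattern (h = 0) is always included.
// [[Rcpp::export(name = ".min_h_over_tuples")]]
NumericVector min_h_over_tuples(IntegerMatrix tuples, double J,
                                NumericVector mu1, NumericVector mu2) {
  int m = tuples.nrow(), npts = mu1.size();
  std::vector<double> e(m), r1(m), r2(m);
  for (int r = 0; r < m; ++r) {
    double area = tuples(r, 4);
    e[r] = (tuples(r, 0) + tuples(r, 1) * J) / area;
    r1[r] = tuples(r, 2) / area;
    r2[r] = tuples(r, 3) / area;
  }
  NumericVector out(npts);
  for (int k = 0; k < npts; ++k) {
    double best = 0.0;  // vacuum
    double m1 = mu1[k], m2 = mu2[k];
    for (int r = 0; r < m; ++r) {
      double h = e[r] - r1[r] * m1 - r2[r] * m2;
      if (h < best) best = h;
    }
    out[k] = best;
  }
  return out;
}
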