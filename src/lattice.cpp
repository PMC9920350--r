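// Triangular-lattice geometry and exact energy kernels.
//
// Sites use 0-based axial coordinates (i, j), i, j in [0, L), mapped to the
// flat index s = i + j*L.  The Euclidean embedding is i*a1 + j*a2 with
// a1 = (1, 0), a2 = (1/2, sqrt(3)/2).  The two interacting shells are the
// six nearest neighbours (distance 1) and the six third-shell neighbours
// (distance 2); the second shell (distance sqrt(3)) carries no interaction.
// Pair energies in J1 units: like pair -1 (first shell), +J (third shell);
// unlike pair +1 (first shell), -J (third shell).  With S in {+1,-1,0} this
// is  -S_x S_y  on the first shell and  +J S_x S_y  on the third.

#include <Rcpp.h>
#include <functional>
#include <map>
#include <vector>
using namespace Rcpp;

static const int DX1[6] = {1, -1, 0, 0, 1, -1};
static const int DY1[6] = {0, 0, 1, -1, -1, 1};
// second shell (distance sqrt(3)); interaction-free but needed for the
// distance<=2 connectivity graph used in raft analysis
static const int DX2[6] = {1, -1, 2, -2, 1, -1};
static const int DY2[6] = {1, -1, -1, 1, -2, 2};

static inline int wrap(int v, int L) { return ((v % L) + L) % L; }
static inline int sid(int i, int j, int L) {
  return wrap(i, L) + wrap(j, L) * L;
}

// [[Rcpp::export(name = ".neighbor_tables")]]
List neighbor_tables(int L) {
  if (L < 5) stop("lattice too small for unambiguous minimum-image shells (need L >= 5)");
  int N = L * L;
  IntegerMatrix nn1(N, 6), nn2(N, 6), nn3(N, 6);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = i + j * L;
      for (int d = 0; d < 6; ++d) {
        nn1(s, d) = sid(i + DX1[d], j + DY1[d], L);
        nn2(s, d) = sid(i + DX2[d], j + DY2[d], L);
        nn3(s, d) = sid(i + 2 * DX1[d], j + 2 * DY1[d], L);
      }
    }
  return List::create(_["nn1"] = nn1, _["nn2"] = nn2, _["nn3"] = nn3);
}

// E = e0 + e1 * J with integer e0 (first shell) and e1 (third shell)
// [[Rcpp::export(name = ".energy_parts")]]
IntegerVector energy_parts(IntegerVector S, int L) {
  int N = L * L;
  if (S.size() != N) stop("S has wrong length");
  long e0 = 0, e1 = 0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = S[i + j * L];
      if (!s) continue;
      for (int d = 0; d < 6; ++d) {
        int v1 = S[sid(i + DX1[d], j + DY1[d], L)];
        if (v1) e0 -= s * v1;
        int v3 = S[sid(i + 2 * DX1[d], j + 2 * DY1[d], L)];
        if (v3) e1 += s * v3;
      }
    }
  // each unordered pair was visited from both ends
  return IntegerVector::create((int)(e0 / 2), (int)(e1 / 2));
}

// (Delta1, Delta2): sums of S over the first and third shells of one site
// [[Rcpp::export(name = ".local_field")]]
IntegerVector local_field_cpp(IntegerVector S, int L, int i, int j) {
  int d1 = 0, d2 = 0;
  for (int d = 0; d < 6; ++d) {
    d1 += S[sid(i + DX1[d], j + DY1[d], L)];
    d2 += S[sid(i + 2 * DX1[d], j + 2 * DY1[d], L)];
  }
  return IntegerVector::create(d1, d2);
}

// Tile a periodic unit cell (HNF sublattice [[a,0],[c,b]]) over an L x L torus.
// celli/cellj/cells give the occupied sites of one cell in cell coordinates.
// [[Rcpp::export(name = ".tile_cell")]]
IntegerVector tile_cell(int L, int a, int b, int cshift,
                        IntegerVector celli, IntegerVector cellj,
                        IntegerVector cells) {
  IntegerVector S(L * L, 0);
  int n = celli.size();
  // reduce every torus site into the cell and look up its occupancy
  std::vector<int> cellS(a * b, 0);
  for (int k = 0; k < n; ++k) {
    int i = celli[k], j = cellj[k];
    if (i < 0 || i >= a || j < 0 || j >= b) stop("cell site out of bounds");
    cellS[i + j * a] = cells[k];
  }
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int jj = ((j % b) + b) % b;
      int k = (j - jj) / b;
      int ii = i - k * cshift;
      ii = ((ii % a) + a) % a;
      S[i + j * L] = cellS[ii + jj * a];
    }
  return S;
}

// Connected components.  mode 1: like-species first-shell adjacency
// (components never join the two species); mode 2: all occupied sites joined
// when within Euclidean distance 2 (shells 1, 2 and 3).
// Returns 0 for empty sites, else a component id (1-based).
// [[Rcpp::export(name = ".lattice_components")]]
IntegerVector lattice_components(IntegerVector S, int L, int mode) {
  int N = L * L;
  std::vector<int> parent(N);
  for (int s = 0; s < N; ++s) parent[s] = s;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int x, int y) {
    x = find(x); y = find(y); if (x != y) parent[x] = y;
  };
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = i + j * L;
      if (!S[s]) continue;
      for (int d = 0; d < 6; ++d) {
        int t1 = sid(i + DX1[d], j + DY1[d], L);
        if (S[t1] && (mode == 2 || S[t1] == S[s])) unite(s, t1);
        if (mode == 2) {
          int t2 = sid(i + DX2[d], j + DY2[d], L);
          if (S[t2]) unite(s, t2);
          int t3 = sid(i + 2 * DX1[d], j + 2 * DY1[d], L);
          if (S[t3]) unite(s, t3);
        }
      }
    }
  IntegerVector comp(N, 0);
  std::map<int, int> relabel;
  for (int s = 0; s < N; ++s) {
    if (!S[s]) continue;
    int r = find(s);
    auto it = relabel.find(r);
    int id;
    if (it == relabel.end()) { id = (int)relabel.size() + 1; relabel[r] = id; }
    else id = it->second;
    comp[s] = id;
  }
  return comp;
}

// Pair-count fingerprint: for each shell (first, third) count like and unlike
// occupied pairs, each pair once.  Used by order_parameters().
// [[Rcpp::export(name = ".pair_counts")]]
IntegerVector pair_counts(IntegerVector S, int L) {
  long like1 = 0, unlike1 = 0, like3 = 0, unlike3 = 0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      int s = S[i + j * L];
      if (!s) continue;
      for (int d = 0; d < 6; ++d) {
        int v1 = S[sid(i + DX1[d], j + DY1[d], L)];
        if (v1) { if (v1 == s) ++like1; else ++unlike1; }
        int v3 = S[sid(i + 2 * DX1[d], j + 2 * DY1[d], L)];
        if (v3) { if (v3 == s) ++like3; else ++unlike3; }
      }
    }
  return IntegerVector::create((int)(like1 / 2), (int)(unlike1 / 2),
                               (int)(like3 / 2), (int)(unlike3 / 2));
}
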