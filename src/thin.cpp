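// Zhang-Suen thinning with a sequential simple-point cleanup.
// Mirrors the reference semantics documented in R/skeleton.R: parallel
// two-subiteration thinning, then sequential deletion of non-endpoint
// pixels whose foreground neighbors form a single 8-connected component.

#include <Rcpp.h>
using namespace Rcpp;

// neighbor offsets P2..P9, clockwise from north, as (dr, dc)
static const int NB[8][2] = {{-1, 0}, {-1, 1}, {0, 1}, {1, 1},
                             {1, 0},  {1, -1}, {0, -1}, {-1, -1}};

static inline int at(const std::vector<int>& m, int nr, int r, int c) {
  return m[(size_t)c * nr + r];
}

// number of 8-connected components among the foreground ring cells
static int nbr_components(const int v[8]) {
  int comp[8];
  int n = 0;
  for (int i = 0; i < 8; ++i) comp[i] = v[i] ? i : -1;
  for (int i = 0; i < 8; ++i) {
    if (!v[i]) continue;
    ++n;
    for (int j = i + 1; j < 8; ++j) {
      if (!v[j]) continue;
      int dr = NB[i][0] - NB[j][0], dc = NB[i][1] - NB[j][1];
      if (std::abs(dr) <= 1 && std::abs(dc) <= 1) {
        int a = comp[i], b = comp[j];
        if (a != b) {
          for (int k = 0; k < 8; ++k)
            if (comp[k] == std::max(a, b)) comp[k] = std::min(a, b);
        }
      }
    }
  }
  int uniq = 0;
  bool seen[8] = {false, false, false, false, false, false, false, false};
  for (int i = 0; i < 8; ++i)
    if (v[i] && !seen[comp[i]]) { seen[comp[i]] = true; ++uniq; }
  (void)n;
  return uniq;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  const int nr = input.nrow(), nc = input.ncol();
  std::vector<int> m((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (input(r, c)) m[(size_t)c * nr + r] = 1;

  auto nbrs = [&](int r, int c, int v[8]) {
    for (int k = 0; k < 8; ++k) {
      int rr = r + NB[k][0], cc = c + NB[k][1];
      v[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? at(m, nr, rr, cc) : 0;
    }
  };

  std::vector<size_t> del;
  del.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!at(m, nr, r, c)) continue;
          int v[8];
          nbrs(r, c, v);
          int B = 0;
          for (int k = 0; k < 8; ++k) B += v[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (v[k] == 0 && v[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          // v[0]=P2(N), v[2]=P4(E), v[4]=P6(S), v[6]=P8(W)
          bool ok;
          if (sub == 0)
            ok = (v[0] * v[2] * v[4] == 0) && (v[2] * v[4] * v[6] == 0);
          else
            ok = (v[0] * v[2] * v[6] == 0) && (v[0] * v[4] * v[6] == 0);
          if (ok) del.push_back((size_t)c * nr + r);
        }
      }
      if (!del.empty()) {
        for (size_t i = 0; i < del.size(); ++i) m[del[i]] = 0;
        changed = true;
      }
    }
  }

  // sequential simple-point cleanup of 2-px staircase leftovers
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!at(m, nr, r, c)) continue;
        int v[8];
        nbrs(r, c, v);
        int B = 0;
        for (int k = 0; k < 8; ++k) B += v[k];
        if (B < 2 || B > 6) continue;
        if (nbr_components(v) == 1) {
          m[(size_t)c * nr + r] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = at(m, nr, r, c) != 0;
  return out;
}
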