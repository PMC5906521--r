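#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving skeletonisation (Guo-Hall two-subiteration
// thinning) and trace-based pruning of short terminal spurs.  Both
// operate on 0/1 rasters; skeleton analysis uses 8-connectivity.

static inline int at(const std::vector<unsigned char> &m, int n, int i,
                     int j) {
  if (i < 0 || i >= n || j < 0) return 0;
  if (j >= (int) (m.size() / n)) return 0;
  return m[i + (size_t) j * n];
}

// one Guo-Hall subiteration; returns number of deleted pixels
static int gh_subiter(std::vector<unsigned char> &m, int nr, int nc,
                      int iter) {
  std::vector<unsigned char> del(m.size(), 0);
  int ndel = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m[i + (size_t) j * nr]) continue;
      // neighbours: p2 = N, p3 = NE, p4 = E, p5 = SE, p6 = S, p7 = SW,
      // p8 = W, p9 = NW (rows grow southwards, cols grow eastwards)
      int p2 = at(m, nr, i - 1, j),     p3 = at(m, nr, i - 1, j + 1);
      int p4 = at(m, nr, i,     j + 1), p5 = at(m, nr, i + 1, j + 1);
      int p6 = at(m, nr, i + 1, j),     p7 = at(m, nr, i + 1, j - 1);
      int p8 = at(m, nr, i,     j - 1), p9 = at(m, nr, i - 1, j - 1);
      int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
              ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
      int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
      int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
      int N = N1 < N2 ? N1 : N2;
      int mcond = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                              : ((p2 | p3 | (!p5)) & p4);
      if (C == 1 && N >= 2 && N <= 3 && mcond == 0) {
        del[i + (size_t) j * nr] = 1;
        ++ndel;
      }
    }
  }
  if (ndel)
    for (size_t k = 0; k < m.size(); ++k)
      if (del[k]) m[k] = 0;
  return ndel;
}

// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> m((size_t) nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + (size_t) j * nr] = mask(i, j) ? 1 : 0;

  for (;;) {
    int d = gh_subiter(m, nr, nc, 0);
    d += gh_subiter(m, nr, nc, 1);
    if (d == 0) break;
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m[i + (size_t) j * nr] != 0;
  return out;
}

static int degree8(const std::vector<unsigned char> &m, int nr, int nc,
                   int i, int j) {
  int d = 0;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      if (di == 0 && dj == 0) continue;
      int r = i + di, c = j + dj;
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (m[r + (size_t) c * nr]) ++d;
    }
  return d;
}

// Remove terminal branches shorter than min_len pixels.  Each endpoint
// (degree-1 pixel) is walked inwards along degree-<=2 pixels; if a
// junction (degree >= 3) is met before min_len steps the walked pixels
// are deleted.  Passes repeat until no spur is removed, so junctions
// exposed by a deletion are themselves cleaned up.
// [[Rcpp::export(name = ".prune_spurs")]]
LogicalMatrix prune_spurs(LogicalMatrix skel, int min_len) {
  const int nr = skel.nrow(), nc = skel.ncol();
  std::vector<unsigned char> m((size_t) nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + (size_t) j * nr] = skel(i, j) ? 1 : 0;
  if (min_len > 0) {
    bool changed = true;
    while (changed) {
      changed = false;
      std::vector<std::pair<int, int> > ends;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (m[i + (size_t) j * nr] && degree8(m, nr, nc, i, j) == 1)
            ends.push_back(std::make_pair(i, j));
      for (size_t e = 0; e < ends.size(); ++e) {
        int ci = ends[e].first, cj = ends[e].second;
        if (!m[ci + (size_t) cj * nr]) continue;  // consumed already
        std::vector<std::pair<int, int> > path;
        int pi = -9, pj = -9;
        bool hit_junction = false;
        while ((int) path.size() < min_len) {
          path.push_back(std::make_pair(ci, cj));
          // successor: the 8-neighbour that is not where we came from
          int ni = -1, nj = -1, nsucc = 0;
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0) continue;
              int r = ci + di, c = cj + dj;
              if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
              if (!m[r + (size_t) c * nr]) continue;
              if (r == pi && c == pj) continue;
              ni = r; nj = c; ++nsucc;
            }
          if (nsucc == 0) break;  // isolated path, keep
          if (nsucc > 1 || degree8(m, nr, nc, ni, nj) >= 3) {
            hit_junction = true;  // next pixel is (at) a junction
            break;
          }
          pi = ci; pj = cj; ci = ni; cj = nj;
        }
        if (hit_junction && (int) path.size() < min_len) {
          for (size_t t = 0; t < path.size(); ++t)
            m[path[t].first + (size_t) path[t].second * nr] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m[i + (size_t) j * nr] != 0;
  return out;
}

// [[Rcpp::export(name = ".neighbour_degree8")]]
IntegerMatrix neighbour_degree8(LogicalMatrix skel) {
  const int nr = skel.nrow(), nc = skel.ncol();
  std::vector<unsigned char> m((size_t) nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + (size_t) j * nr] = skel(i, j) ? 1 : 0;
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m[i + (size_t) j * nr] ? degree8(m, nr, nc, i, j)
                                         : NA_INTEGER;
  return out;
}
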