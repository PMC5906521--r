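#include <Rcpp.h>
using namespace Rcpp;

// One cellular-automaton sweep.  Cells present at sweep start are visited
// once, in a fresh uniformly random permutation; cells created during the
// sweep are not revisited.  Per visited cell with at least one empty von
// Neumann neighbour the RNG is consumed in a fixed, documented order:
//   1. action draw  (move with probability p_move, else division)
//   2. division-gate draw (division proposals only)
//   3. site draw    (softmax over the empty neighbours)
// All draws come from R's RNG stream, so set.seed() makes sweeps
// reproducible across platforms.  Off-grid neighbours are unavailable;
// moves are always carried out (subject to the optional attachment rule),
// divisions only if the gate succeeds.

static const int DR[4] = {-1, 1, 0, 0};  // up, down, left, right
static const int DC[4] = {0, 0, -1, 1};

// [[Rcpp::export(name = ".ca_sweep")]]
List ca_sweep(LogicalMatrix occupancy, NumericMatrix g, double p_move,
              double c1, double c2, double beta_move, double beta_div,
              bool gdnf_division, double p_const, bool attachment_rule) {
  const int n = occupancy.nrow();
  if (occupancy.ncol() != n) stop("occupancy raster must be square");
  if (g.nrow() != n || g.ncol() != n)
    stop("field and occupancy raster shapes differ");

  LogicalMatrix occ = clone(occupancy);

  // cells at sweep start, column-major scan
  std::vector<int> rows, cols;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (occ(i, j)) { rows.push_back(i); cols.push_back(j); }
  const int ncell = (int) rows.size();
  if (ncell == 0)
    return List::create(_["occupancy"] = occ, _["divisions"] = 0,
                        _["moves"] = 0);

  IntegerVector perm = Rcpp::sample(ncell, ncell, false);  // 1-based

  int n_div = 0, n_move = 0;
  int er[4], ec[4];
  double w[4];

  for (int v = 0; v < ncell; ++v) {
    const int i = rows[perm[v] - 1], j = cols[perm[v] - 1];
    if (!occ(i, j)) continue;  // moved away earlier in this sweep

    // empty von Neumann neighbours
    int K = 0;
    for (int d = 0; d < 4; ++d) {
      int r = i + DR[d], c = j + DC[d];
      if (r < 0 || r >= n || c < 0 || c >= n) continue;
      if (!occ(r, c)) { er[K] = r; ec[K] = c; ++K; }
    }
    if (K == 0) continue;

    const bool is_move = (unif_rand() < p_move);

    bool place = true;
    double beta = beta_move;
    if (!is_move) {
      beta = beta_div;
      double p_cd = gdnf_division
        ? R::pnorm(c1 + c2 * g(i, j), 0.0, 1.0, 1, 0)
        : p_const;
      place = (unif_rand() < p_cd);
      if (!place) continue;  // failed gate: no retry as a move
    }

    // softmax site selection over the K empty neighbours
    double gmax = g(er[0], ec[0]);
    for (int d = 1; d < K; ++d)
      if (g(er[d], ec[d]) > gmax) gmax = g(er[d], ec[d]);
    double tot = 0.0;
    for (int d = 0; d < K; ++d) {
      w[d] = std::exp(beta * (g(er[d], ec[d]) - gmax));
      tot += w[d];
    }
    double u = unif_rand() * tot, acc = 0.0;
    int pick = K - 1;
    for (int d = 0; d < K; ++d) {
      acc += w[d];
      if (u < acc) { pick = d; break; }
    }
    const int ri = er[pick], ci = ec[pick];

    if (is_move) {
      if (attachment_rule) {
        // destination must touch at least one cell other than the mover
        int contacts = 0;
        for (int d = 0; d < 4; ++d) {
          int r = ri + DR[d], c = ci + DC[d];
          if (r < 0 || r >= n || c < 0 || c >= n) continue;
          if ((r != i || c != j) && occ(r, c)) ++contacts;
        }
        if (contacts == 0) continue;  // move rejected, cell stays
      }
      occ(i, j) = false;
      occ(ri, ci) = true;
      ++n_move;
    } else {
      occ(ri, ci) = true;  // daughter cell
      ++n_div;
    }
  }

  return List::create(_["occupancy"] = occ, _["divisions"] = n_div,
                      _["moves"] = n_move);
}
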