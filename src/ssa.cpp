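#include <Rcpp.h>
using namespace Rcpp;

// Direct Gillespie simulation of the H/D subunit-exchange network.
//
// TTR tetramers are dimers of dimers: each tetramer is tracked by its
// unordered pair of constituent dimers, and dissociation returns exactly
// those two dimers. Subunits scramble only at the dimer <-> monomer level.
//
// State vector (copy numbers):
//   0..5  tetramers by dimer pair: (HH,HH)=4H, (HH,HD)=3H1D, (HH,DD) and
//         (HD,HD) = the two 2H2D assemblies, (HD,DD)=1H3D, (DD,DD)=4D
//   6..8  dimers HH, HD, DD (0..2 deuterated subunits)
//   9..10 monomers H, D
//
// Every propensity is multiplied by iso^(number of D subunits among the
// reactants). Uses R's RNG so results are reproducible under set.seed().

static inline double pair_count(double n) { return n * (n - 1.0) / 2.0; }

// [[Rcpp::export]]
NumericMatrix ssa_exchange_cpp(NumericVector counts0, double k_td, double k_ta,
                               double k_dd, double k_da, double iso,
                               NumericVector t_grid) {
  const int n_grid = t_grid.size();
  NumericMatrix out(n_grid, 11);
  double x[11];
  for (int i = 0; i < 11; ++i) x[i] = counts0[i];

  double isod[5];
  isod[0] = 1.0;
  for (int d = 1; d < 5; ++d) isod[d] = isod[d - 1] * iso;

  // tetramer channels: constituent dimer types (by D count 0..2)
  const int tp_i[6] = {0, 0, 0, 1, 1, 2};
  const int tp_j[6] = {0, 1, 2, 1, 2, 2};
  // dimer association channels: monomer partners
  const int da_i[3] = {9, 9, 10};
  const int da_j[3] = {9, 10, 10};

  double t = 0.0;
  int g = 0;
  double a[18];

  for (;;) {
    // 0..5: tetramer dissociation into its two constituent dimers
    for (int c = 0; c < 6; ++c)
      a[c] = k_td * isod[tp_i[c] + tp_j[c]] * x[c];
    // 6..11: tetramer association from dimer pairs
    for (int c = 0; c < 6; ++c) {
      int i = 6 + tp_i[c], j = 6 + tp_j[c];
      double n = (i == j) ? pair_count(x[i]) : x[i] * x[j];
      a[6 + c] = k_ta * isod[tp_i[c] + tp_j[c]] * n;
    }
    // 12..14: dimer dissociation
    for (int d = 0; d < 3; ++d) a[12 + d] = k_dd * isod[d] * x[6 + d];
    // 15..17: dimer association from monomer pairs
    for (int c = 0; c < 3; ++c) {
      int i = da_i[c], j = da_j[c];
      double n = (i == j) ? pair_count(x[i]) : x[i] * x[j];
      a[15 + c] = k_da * isod[(i - 9) + (j - 9)] * n;
    }
    double a0 = 0.0;
    for (int c = 0; c < 18; ++c) a0 += a[c];

    double t_next = (a0 > 0.0) ? t - std::log(unif_rand()) / a0 : R_PosInf;

    while (g < n_grid && t_grid[g] < t_next) {
      for (int i = 0; i < 11; ++i) out(g, i) = x[i];
      ++g;
    }
    if (g >= n_grid) break;
    t = t_next;

    double u = unif_rand() * a0;
    int c = 0;
    for (; c < 17; ++c) { if (u < a[c]) break; u -= a[c]; }

    if (c < 6) {
      x[c] -= 1.0;
      x[6 + tp_i[c]] += 1.0;
      x[6 + tp_j[c]] += 1.0;
    } else if (c < 12) {
      int k = c - 6;
      x[6 + tp_i[k]] -= 1.0;
      x[6 + tp_j[k]] -= 1.0;
      x[k] += 1.0;
    } else if (c < 15) {
      int d = c - 12;
      x[6 + d] -= 1.0;
      switch (d) {
      case 0: x[9] += 2.0; break;                 // HH -> 2 H
      case 1: x[9] += 1.0; x[10] += 1.0; break;   // HD -> H + D
      default: x[10] += 2.0; break;               // DD -> 2 D
      }
    } else {
      int i = da_i[c - 15], j = da_j[c - 15];
      x[i] -= 1.0; x[j] -= 1.0;
      x[6 + (i - 9) + (j - 9)] += 1.0;
    }
  }
  return out;
}
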