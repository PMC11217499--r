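#include <Rcpp.h>
using namespace Rcpp;

// Band counts for the pair correlation function: for each origin i, count
// targets j with r_k < d_ij <= r_k + dr per band (half-open upward band
// convention). origin_idx maps each origin to its index in the target set
// (0-based) so that self-pairs are skipped when origins are a guarded
// subset of the targets; -1 means the origin is not a target.
// [[Rcpp::export]]
IntegerVector pcf_band_counts_cpp(NumericVector ox, NumericVector oy,
                                  NumericVector tx, NumericVector ty,
                                  double dr, int nbands,
                                  IntegerVector origin_idx) {
  const int n = ox.size(), m = tx.size();
  const double rmax = dr * nbands;
  const double rmax2 = rmax * rmax;
  IntegerVector counts(nbands);
  for (int i = 0; i < n; ++i) {
    const double xi = ox[i], yi = oy[i];
    const int self = origin_idx[i];
    for (int j = 0; j < m; ++j) {
      if (j == self) continue;
      const double dx = tx[j] - xi, dy = ty[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2 || d2 == 0.0) continue;  // d == 0: below every band
      // band k (0-based) holds (k*dr, (k+1)*dr]; ties on the upper edge
      // stay in band k.
      const double d = std::sqrt(d2);
      int k = (int)std::ceil(d / dr) - 1;
      if (k < 0) k = 0;
      if (k >= nbands) continue;
      ++counts[k];
    }
  }
  return counts;
}

// Exact nearest-neighbour Euclidean distance from every origin to the
// target set, skipping the origin's own record when origin_idx >= 0.
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericVector ox, NumericVector oy,
                          NumericVector tx, NumericVector ty,
                          IntegerVector origin_idx) {
  const int n = ox.size(), m = tx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = ox[i], yi = oy[i];
    const int self = origin_idx[i];
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      if (j == self) continue;
      const double dx = tx[j] - xi, dy = ty[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
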