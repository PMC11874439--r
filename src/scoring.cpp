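#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Five Vina-form pair terms as a function of surface distance ds and the
// pair's hydrophobic / donor-acceptor eligibility. Slopes returned for the
// analytic gradient; sub-gradient 0 at the piecewise-linear kinks.
static inline void pair_terms(double ds, bool hyd_pair, bool hb_pair,
                              double* t, double* dt) {
  double g1 = std::exp(-(ds / 0.5) * (ds / 0.5));
  double g2 = std::exp(-((ds - 3.0) / 2.0) * ((ds - 3.0) / 2.0));
  t[0] = g1;
  t[1] = g2;
  dt[0] = -8.0 * ds * g1;
  dt[1] = -0.5 * (ds - 3.0) * g2;
  if (ds < 0) { t[2] = ds * ds; dt[2] = 2.0 * ds; } else { t[2] = 0; dt[2] = 0; }
  t[3] = 0; dt[3] = 0;
  if (hyd_pair) {
    if (ds <= 0.5) t[3] = 1.0;
    else if (ds < 1.5) { t[3] = 1.5 - ds; dt[3] = -1.0; }
  }
  t[4] = 0; dt[4] = 0;
  if (hb_pair) {
    if (ds <= -0.7) t[4] = 1.0;
    else if (ds < 0) { t[4] = -ds / 0.7; dt[4] = -1.0 / 0.7; }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_terms(NumericVector dsurf, LogicalVector hydPair,
                             LogicalVector hbPair) {
  int n = dsurf.size();
  NumericMatrix out(n, 5);
  double t[5], dt[5];
  for (int i = 0; i < n; ++i) {
    pair_terms(dsurf[i], hydPair[i], hbPair[i], t, dt);
    for (int k = 0; k < 5; ++k) out(i, k) = t[k];
  }
  colnames(out) = CharacterVector::create("gauss1", "gauss2", "repulsion",
                                          "hydrophobic", "hbond");
  return out;
}

// Receptor-ligand interaction score over all heavy-atom pairs within the
// center-to-center cutoff. Returns per-term sums, the weighted total and
// (optionally) d(weighted)/d(ligand coordinates).
// Atom roles are passed as small integer flag vectors: active (heavy,
// scored), hydrophobic-C, donor, acceptor.
// [[Rcpp::export]]
List cpp_score_inter(NumericMatrix L, NumericVector Lvdw, IntegerVector Lact,
                     IntegerVector Lhyd, IntegerVector Ldon, IntegerVector Lacc,
                     NumericMatrix R, NumericVector Rvdw, IntegerVector Ract,
                     IntegerVector Rhyd, IntegerVector Rdon, IntegerVector Racc,
                     NumericVector w, double cutoff, bool grad) {
  int nl = L.nrow(), nr = R.nrow();
  double sums[5] = {0, 0, 0, 0, 0};
  NumericMatrix G(grad ? nl : 0, 3);
  double t[5], dt[5];
  double cut2 = cutoff * cutoff;
  long npairs = 0;
  for (int i = 0; i < nl; ++i) {
    if (!Lact[i]) continue;
    double xi = L(i, 0), yi = L(i, 1), zi = L(i, 2);
    for (int j = 0; j < nr; ++j) {
      if (!Ract[j]) continue;
      double dx = xi - R(j, 0), dy = yi - R(j, 1), dz = zi - R(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      double d = std::sqrt(d2);
      double ds = d - (Lvdw[i] + Rvdw[j]);
      bool hyd = Lhyd[i] && Rhyd[j];
      bool hb = (Ldon[i] && Racc[j]) || (Lacc[i] && Rdon[j]);
      pair_terms(ds, hyd, hb, t, dt);
      ++npairs;
      double dWdds = 0;
      for (int k = 0; k < 5; ++k) { sums[k] += t[k]; dWdds += w[k] * dt[k]; }
      if (grad && d > 1e-9) {
        double f = dWdds / d;
        G(i, 0) += f * dx; G(i, 1) += f * dy; G(i, 2) += f * dz;
      }
    }
  }
  double weighted = 0;
  NumericVector termSums(5);
  for (int k = 0; k < 5; ++k) { termSums[k] = sums[k]; weighted += w[k] * sums[k]; }
  termSums.names() = CharacterVector::create("gauss1", "gauss2", "repulsion",
                                             "hydrophobic", "hbond");
  List out = List::create(_["terms"] = termSums, _["weighted"] = weighted,
                          _["npairs"] = (double)npairs);
  if (grad) out["grad"] = G;
  return out;
}

// Intramolecular ligand score over a precomputed pair list (pairs whose
// separation crosses a rotatable bond and are 1-4 or further apart).
// [[Rcpp::export]]
List cpp_score_intra(NumericMatrix X, NumericVector vdw, IntegerVector hyd,
                     IntegerVector don, IntegerVector acc, IntegerMatrix pairs,
                     NumericVector w, double cutoff, bool grad) {
  int np = pairs.nrow(), n = X.nrow();
  double sums[5] = {0, 0, 0, 0, 0};
  NumericMatrix G(grad ? n : 0, 3);
  double t[5], dt[5];
  double cut2 = cutoff * cutoff;
  for (int k = 0; k < np; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1), dz = X(i, 2) - X(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > cut2) continue;
    double d = std::sqrt(d2);
    double ds = d - (vdw[i] + vdw[j]);
    bool hp = hyd[i] && hyd[j];
    bool hb = (don[i] && acc[j]) || (acc[i] && don[j]);
    pair_terms(ds, hp, hb, t, dt);
    double dWdds = 0;
    for (int q = 0; q < 5; ++q) { sums[q] += t[q]; dWdds += w[q] * dt[q]; }
    if (grad && d > 1e-9) {
      double f = dWdds / d;
      G(i, 0) += f * dx; G(i, 1) += f * dy; G(i, 2) += f * dz;
      G(j, 0) -= f * dx; G(j, 1) -= f * dy; G(j, 2) -= f * dz;
    }
  }
  double weighted = 0;
  NumericVector termSums(5);
  for (int q = 0; q < 5; ++q) { termSums[q] = sums[q]; weighted += w[q] * sums[q]; }
  List out = List::create(_["terms"] = termSums, _["weighted"] = weighted);
  if (grad) out["grad"] = G;
  return out;
}
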