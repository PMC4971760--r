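#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for read-to-transcript assignments under a
// Dirichlet prior.  Alignments are stored CSR-style: entries for read r are
// aln_tx[offsets[r] .. offsets[r+1]-1] (0-based transcript indices, one
// entry per (transcript, position) alignment).  The full conditional for a
// read is P(z_r = entry with transcript i) ~ (alpha_i + n_i^{-r}) / l_i.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export(name = ".gibbs_sample")]]
List gibbs_sample(IntegerVector aln_tx, IntegerVector offsets,
                  NumericVector inv_eff, NumericVector alpha,
                  NumericVector init_weight, int burn_in, int n_samples) {
  const int n_reads = offsets.size() - 1;
  const int M = inv_eff.size();
  std::vector<double> n(M, 0.0);
  std::vector<int> z(n_reads);

  // initial assignment: one draw per read from the supplied weights
  for (int r = 0; r < n_reads; ++r) {
    const int lo = offsets[r], hi = offsets[r + 1];
    double tot = 0.0;
    for (int k = lo; k < hi; ++k) tot += init_weight[k];
    double u = unif_rand() * tot;
    int pick = hi - 1;
    double acc = 0.0;
    for (int k = lo; k < hi; ++k) {
      acc += init_weight[k];
      if (u <= acc) { pick = k; break; }
    }
    z[r] = pick;
    n[aln_tx[pick]] += 1.0;
  }

  std::vector<double> sum_n(M, 0.0);
  std::vector<double> w;
  const int total = burn_in + n_samples;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int r = 0; r < n_reads; ++r) {
      const int lo = offsets[r], hi = offsets[r + 1];
      const int old_tx = aln_tx[z[r]];
      n[old_tx] -= 1.0;
      if (hi - lo == 1) {            // unique read: nothing to resample
        n[old_tx] += 1.0;
        continue;
      }
      double tot = 0.0;
      w.resize(hi - lo);
      for (int k = lo; k < hi; ++k) {
        const int i = aln_tx[k];
        w[k - lo] = (alpha[i] + n[i]) * inv_eff[i];
        tot += w[k - lo];
      }
      double u = unif_rand() * tot;
      int pick = hi - 1;
      double acc = 0.0;
      for (int k = lo; k < hi; ++k) {
        acc += w[k - lo];
        if (u <= acc) { pick = k; break; }
      }
      z[r] = pick;
      n[aln_tx[pick]] += 1.0;
    }
    if (sweep >= burn_in)
      for (int i = 0; i < M; ++i) sum_n[i] += n[i];
    if (sweep % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector mean_n(M);
  for (int i = 0; i < M; ++i) mean_n[i] = sum_n[i] / n_samples;
  return List::create(_["mean_count"] = mean_n);
}
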