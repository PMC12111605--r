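#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// One diploid Wright-Fisher generation: viability selection (additive,
// fitness 1 / 1+s / 1+2s at sweep_idx), parents drawn with replacement
// proportional to fitness, each gamete recombined with Poisson(lambda)
// crossovers uniform on the chromosome. All randomness comes from R's
// RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_generation_cpp(const IntegerMatrix& haps,
                                const NumericVector& pos,
                                double chrom_length, double lambda,
                                int sweep_idx, double s) {
  const int twoN = haps.nrow(), m = haps.ncol(), N = twoN / 2;
  std::vector<double> cw(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (s != 0.0) {
      int g = haps(2 * i, sweep_idx) + haps(2 * i + 1, sweep_idx);
      w = 1.0 + s * g;
    }
    tot += w;
    cw[i] = tot;
  }
  IntegerMatrix out(twoN, m);
  std::vector<double> breaks;
  for (int k = 0; k < twoN; ++k) {
    double u = R::unif_rand() * tot;
    int parent = std::lower_bound(cw.begin(), cw.end(), u) - cw.begin();
    if (parent >= N) parent = N - 1;
    int phase = (R::unif_rand() < 0.5) ? 0 : 1;
    int i1 = 2 * parent + phase, i2 = 2 * parent + 1 - phase;
    int nx = (int)R::rpois(lambda);
    if (nx == 0) {
      for (int j = 0; j < m; ++j) out(k, j) = haps(i1, j);
    } else {
      breaks.resize(nx);
      for (int b = 0; b < nx; ++b) breaks[b] = R::unif_rand() * chrom_length;
      std::sort(breaks.begin(), breaks.end());
      int b = 0, parity = 0;
      for (int j = 0; j < m; ++j) {
        while (b < nx && breaks[b] < pos[j]) { parity ^= 1; ++b; }
        out(k, j) = parity == 0 ? haps(i1, j) : haps(i2, j);
      }
    }
  }
  return out;
}
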