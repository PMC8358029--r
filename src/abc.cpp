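// Simulation kernel for the rejection-ABC estimate of the lake-migrant
// proportion: for each candidate lambda, mix the before-flood and lake
// allele frequencies, resample read counts binomially at the observed
// depths, and return the summary statistics of the simulated frequency
// distribution (mean, median, fraction exactly 0, fraction below a low
// threshold).  Uses R's RNG.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix abc_sim_summaries_cpp(NumericVector p_before,
                                    NumericVector p_lake,
                                    IntegerVector depth,
                                    NumericVector lambda,
                                    double low_thresh) {
  int S = (int)p_before.size();
  if ((int)p_lake.size() != S || (int)depth.size() != S)
    stop("p_before, p_lake and depth must have equal length");
  int n_sim = (int)lambda.size();
  NumericMatrix out(n_sim, 4);
  std::vector<double> f((size_t)S);
  for (int j = 0; j < n_sim; ++j) {
    double lam = lambda[j];
    double sum = 0;
    int n_zero = 0, n_low = 0;
    for (int i = 0; i < S; ++i) {
      double pm = lam * p_lake[i] + (1 - lam) * p_before[i];
      double k = R::rbinom((double)depth[i], pm);
      double fr = k / depth[i];
      f[i] = fr;
      sum += fr;
      if (k == 0) ++n_zero;
      if (fr < low_thresh) ++n_low;
    }
    std::sort(f.begin(), f.end());
    double med = (S % 2) ? f[S / 2] : 0.5 * (f[S / 2 - 1] + f[S / 2]);
    out(j, 0) = sum / S;
    out(j, 1) = med;
    out(j, 2) = (double)n_zero / S;
    out(j, 3) = (double)n_low / S;
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
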