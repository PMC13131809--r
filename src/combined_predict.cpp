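#include <Rcpp.h>
using namespace Rcpp;

// Predicted "jumped" probability of the combined model for a batch of trials.
//
// The Bayesian component evaluates the non-central chi-square tail above the
// squared criterion for the trial's condition and cued prior; the perceptron
// component blurs a per-prior association curve (psi at the input-grid bin
// centers) with the condition's truncated-Gaussian population code. This is
// the inner loop of the 12-parameter maximum-likelihood fit, so it is
// compiled; an R reference implementation is cross-checked in the tests.
//
// cond and prior_idx are 1-based indices into the per-condition sigmas and
// the bank columns respectively.
// [[Rcpp::export]]
NumericVector combined_predict_cpp(NumericVector x,
                                   IntegerVector cond,
                                   IntegerVector prior_idx,
                                   NumericVector sigma_t,
                                   NumericVector sigma_nj,
                                   double sigma_j,
                                   NumericVector priors,
                                   double sigma_t_bayes,
                                   double w_bayes,
                                   NumericMatrix banks,
                                   NumericVector centers,
                                   double range_lo,
                                   double range_hi) {
  const int n = x.size();
  const int nbin = centers.size();
  const int ncond = sigma_t.size();
  const int nprior = priors.size();
  NumericVector out(n);

  // squared criterion per condition x prior
  std::vector<double> xc2(ncond * nprior);
  const double st2b = sigma_t_bayes * sigma_t_bayes;
  for (int c = 0; c < ncond; ++c) {
    const double vj = sigma_j * sigma_j + st2b;
    const double vn = sigma_nj[c] * sigma_nj[c] + st2b;
    for (int p = 0; p < nprior; ++p) {
      const double num = std::log(vj / vn) +
        2.0 * std::log((1.0 - priors[p]) / priors[p]);
      const double den = 1.0 / vn - 1.0 / vj;
      xc2[c * nprior + p] = num / den;
    }
  }
  // df = 1: the non-central chi-square tail above c with non-centrality
  // delta^2 equals P(|Z + delta| > sqrt(c)), evaluated with two normal CDFs
  // (exact, and far cheaper than the series expansion at large delta).

  const double lo = range_lo;
  const double hi = range_hi;
  for (int i = 0; i < n; ++i) {
    const int c = cond[i] - 1;
    const int p = prior_idx[i] - 1;
    double xi = std::fabs(x[i]);
    // Bayesian component
    const double q = xc2[c * nprior + p];
    double ob;
    if (q <= 0.0) {
      ob = 1.0;
    } else {
      const double root = std::sqrt(q) / sigma_t_bayes;
      const double delta = xi / sigma_t_bayes;
      ob = R::pnorm(delta - root, 0.0, 1.0, 1, 0) +
           R::pnorm(-delta - root, 0.0, 1.0, 1, 0);
    }
    // perceptron component: blurred association curve
    double xe = xi < lo ? lo : (xi > hi ? hi : xi);
    const double inv2s2 = 1.0 / (2.0 * sigma_t[c] * sigma_t[c]);
    double wsum = 0.0, psum = 0.0;
    for (int b = 0; b < nbin; ++b) {
      const double d = centers[b] - xe;
      const double w = std::exp(-d * d * inv2s2);
      wsum += w;
      psum += w * banks(b, p);
    }
    const double op = psum / wsum;
    out[i] = w_bayes * ob + (1.0 - w_bayes) * op;
  }
  return out;
}
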