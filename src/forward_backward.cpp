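#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a discrete-state HMM given the
// per-timepoint log emission densities. Returns posterior marginals
// (gamma), the summed pairwise posteriors (xi_sum, used by the Baum-Welch
// M-step for the transition matrix) and the data log-likelihood.
// [[Rcpp::export(name = ".forwardBackwardCpp")]]
List forwardBackwardCpp(NumericMatrix logB, NumericVector pi,
                        NumericMatrix Theta) {
  const int T = logB.nrow();
  const int n = logB.ncol();
  NumericMatrix alpha(T, n), beta(T, n), gamma(T, n), xisum(n, n);
  NumericVector c(T);      // per-step scaling factors
  NumericVector rowmax(T); // log-space offsets for the emissions
  std::vector<double> b(T * n);

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < n; ++k) m = std::max(m, logB(t, k));
    rowmax[t] = m;
    for (int k = 0; k < n; ++k) b[t * n + k] = std::exp(logB(t, k) - m);
  }

  // forward
  double s = 0.0;
  for (int k = 0; k < n; ++k) {
    alpha(0, k) = pi[k] * b[k];
    s += alpha(0, k);
  }
  if (s <= 0) stop("forward pass underflow at t = 0");
  c[0] = s;
  for (int k = 0; k < n; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < n; ++k) {
      double a = 0.0;
      for (int l = 0; l < n; ++l) a += alpha(t - 1, l) * Theta(l, k);
      a *= b[t * n + k];
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) stop("forward pass underflow");
    c[t] = s;
    for (int k = 0; k < n; ++k) alpha(t, k) /= s;
  }

  // backward
  for (int k = 0; k < n; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int l = 0; l < n; ++l) {
      double v = 0.0;
      for (int k = 0; k < n; ++k)
        v += Theta(l, k) * b[(t + 1) * n + k] * beta(t + 1, k);
      beta(t, l) = v / c[t + 1];
    }
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < n; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < n; ++k) gamma(t, k) /= g;
  }
  for (int t = 1; t < T; ++t) {
    for (int l = 0; l < n; ++l) {
      for (int k = 0; k < n; ++k) {
        xisum(l, k) += alpha(t - 1, l) * Theta(l, k) * b[t * n + k] *
                       beta(t, k) / c[t];
      }
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + rowmax[t];
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xisum,
                      _["log_likelihood"] = ll);
}
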