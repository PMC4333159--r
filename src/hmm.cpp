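#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a two-state chain.
//
// logemit: n x 2 matrix of per-site log emission likelihoods
//          (column 0 = hypo state, column 1 = hyper state)
// pi:      length-2 initial state probabilities
// A:       2 x 2 transition matrix (rows sum to 1)
//
// Returns the total log-likelihood, the n x 2 posterior state
// probabilities, the 2 x 2 matrix of expected transition counts and the
// posterior at the first site (for initial-probability re-estimation).
// [[Rcpp::export]]
List fb_two_state(NumericMatrix logemit, NumericVector pi, NumericMatrix A) {
  const int n = logemit.nrow();
  if (n == 0) stop("empty chunk");

  // emission likelihoods rescaled per site for numerical stability
  NumericMatrix b(n, 2);
  NumericVector shift(n);
  for (int i = 0; i < n; ++i) {
    double m = std::max(logemit(i, 0), logemit(i, 1));
    shift[i] = m;
    b(i, 0) = std::exp(logemit(i, 0) - m);
    b(i, 1) = std::exp(logemit(i, 1) - m);
  }

  NumericMatrix alpha(n, 2), beta(n, 2);
  NumericVector c(n);

  alpha(0, 0) = pi[0] * b(0, 0);
  alpha(0, 1) = pi[1] * b(0, 1);
  c[0] = alpha(0, 0) + alpha(0, 1);
  if (c[0] <= 0) stop("zero forward probability at site 1");
  alpha(0, 0) /= c[0];
  alpha(0, 1) /= c[0];

  for (int i = 1; i < n; ++i) {
    for (int s = 0; s < 2; ++s) {
      alpha(i, s) = (alpha(i - 1, 0) * A(0, s) + alpha(i - 1, 1) * A(1, s)) *
                    b(i, s);
    }
    c[i] = alpha(i, 0) + alpha(i, 1);
    if (c[i] <= 0) stop("zero forward probability at site %d", i + 1);
    alpha(i, 0) /= c[i];
    alpha(i, 1) /= c[i];
  }

  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int s = 0; s < 2; ++s) {
      beta(i, s) = (A(s, 0) * b(i + 1, 0) * beta(i + 1, 0) +
                    A(s, 1) * b(i + 1, 1) * beta(i + 1, 1)) / c[i + 1];
    }
  }

  NumericMatrix gamma(n, 2);
  for (int i = 0; i < n; ++i) {
    double g0 = alpha(i, 0) * beta(i, 0);
    double g1 = alpha(i, 1) * beta(i, 1);
    double z = g0 + g1;
    gamma(i, 0) = g0 / z;
    gamma(i, 1) = g1 / z;
  }

  NumericMatrix xi(2, 2);
  for (int i = 0; i + 1 < n; ++i) {
    double z = 0.0;
    double e[2][2];
    for (int s = 0; s < 2; ++s) {
      for (int t = 0; t < 2; ++t) {
        e[s][t] = alpha(i, s) * A(s, t) * b(i + 1, t) * beta(i + 1, t) /
                  c[i + 1];
        z += e[s][t];
      }
    }
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2; ++t) xi(s, t) += e[s][t] / z;
  }

  double loglik = 0.0;
  for (int i = 0; i < n; ++i) loglik += std::log(c[i]) + shift[i];

  return List::create(_["loglik"] = loglik, _["posterior"] = gamma,
                      _["xi"] = xi,
                      _["gamma1"] = NumericVector::create(gamma(0, 0),
                                                          gamma(0, 1)));
}
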