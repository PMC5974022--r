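#include <Rcpp.h>
using namespace Rcpp;

// Stochastic gradient descent for L2-penalized logistic loss.
// y in {-1, +1}; order is the concatenated per-epoch visit order
// (0-based), supplied from R so shuffling stays under R's RNG.
// Learning rate schedule: eta_t = eta0 / (1 + alpha * eta0 * t).
// [[Rcpp::export(name = ".sgd_logistic_cpp")]]
NumericVector sgd_logistic_cpp(NumericMatrix X, NumericVector y,
                               IntegerVector order, double alpha,
                               double eta0) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0);
  double b = 0.0;
  long t = 0;
  for (R_xlen_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    if (i < 0 || i >= n) stop("visit order out of range");
    double eta = eta0 / (1.0 + alpha * eta0 * (double)t);
    double margin = b;
    for (int j = 0; j < p; ++j) margin += w[j] * X(i, j);
    margin *= y[i];
    double s = 1.0 / (1.0 + std::exp(margin)); // sigmoid(-margin)
    double shrink = 1.0 - eta * alpha;
    for (int j = 0; j < p; ++j) {
      w[j] = w[j] * shrink + eta * y[i] * X(i, j) * s;
    }
    b += eta * y[i] * s;
    ++t;
  }
  NumericVector out(p + 1);
  out[0] = b;
  for (int j = 0; j < p; ++j) out[j + 1] = w[j];
  return out;
}
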