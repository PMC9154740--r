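// Exact (O(n^2)) t-distributed stochastic neighbor embedding.
//
// Standard formulation: Gaussian input affinities calibrated per point by
// binary search to a target perplexity, symmetrized and normalized;
// Student-t output kernel; gradient descent with momentum, per-parameter
// gains, and early exaggeration.  Random initialization is drawn from R's
// RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static void squared_distances(const NumericMatrix& X, std::vector<double>& D) {
  const int n = X.nrow(), d = X.ncol();
  for (int i = 0; i < n; ++i) {
    D[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      D[(size_t)i * n + j] = s;
      D[(size_t)j * n + i] = s;
    }
  }
}

// [[Rcpp::export(name = ".tsne_exact")]]
NumericMatrix tsne_exact(NumericMatrix X, double perplexity,
                         int max_iter = 1000, double eta = 200.0,
                         double exaggeration = 12.0, int exaggerate_iter = 250,
                         double theta_mom_switch = 250) {
  const int n = X.nrow();
  if (n < 4) stop("too few rows for embedding");
  if (perplexity < 2 || 3 * perplexity > n - 1)
    stop("perplexity must satisfy 2 <= perplexity <= (n-1)/3");

  std::vector<double> D((size_t)n * n);
  squared_distances(X, D);

  // Conditional affinities p_{j|i} at target perplexity via binary search
  // on precision beta_i.
  std::vector<double> P((size_t)n * n, 0.0);
  const double logU = std::log(perplexity);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1e30, betamax = 1e30;
    const double* Di = &D[(size_t)i * n];
    std::vector<double> row(n);
    for (int it = 0; it < 60; ++it) {
      double sum = 0.0;
      for (int j = 0; j < n; ++j) {
        row[j] = (j == i) ? 0.0 : std::exp(-beta * Di[j]);
        sum += row[j];
      }
      if (sum < 1e-300) sum = 1e-300;
      double H = 0.0;
      for (int j = 0; j < n; ++j)
        if (row[j] > 0.0) {
          const double p = row[j] / sum;
          H -= p * std::log(p);
        }
      const double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {           // entropy too high -> sharper kernel
        betamin = beta;
        beta = (betamax > 1e29) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = (betamin < -1e29) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    double sum = 0.0;
    for (int j = 0; j < n; ++j) {
      row[j] = (j == i) ? 0.0 : std::exp(-beta * Di[j]);
      sum += row[j];
    }
    if (sum < 1e-300) sum = 1e-300;
    for (int j = 0; j < n; ++j) P[(size_t)i * n + j] = row[j] / sum;
  }
  // Symmetrize, normalize, floor.
  double psum = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double v = (P[(size_t)i * n + j] + P[(size_t)j * n + i]) / 2.0;
      P[(size_t)i * n + j] = v;
      P[(size_t)j * n + i] = v;
      psum += 2.0 * v;
    }
  for (size_t k = 0; k < P.size(); ++k) {
    P[k] = std::max(P[k] / psum, 1e-12);
    P[k] *= exaggeration;
  }

  std::vector<double> y0(n), y1(n);
  {
    RNGScope scope;
    for (int i = 0; i < n; ++i) {
      y0[i] = R::rnorm(0.0, 1e-4);
      y1[i] = R::rnorm(0.0, 1e-4);
    }
  }
  std::vector<double> dY((size_t)n * 2, 0.0), iY((size_t)n * 2, 0.0),
      gains((size_t)n * 2, 1.0), num((size_t)n * n);

  for (int iter = 0; iter < max_iter; ++iter) {
    // Student-t numerators and normalizer.
    double qsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const double yi0 = y0[i], yi1 = y1[i];
      double* Ni = &num[(size_t)i * n];
      Ni[i] = 0.0;
      double rowsum = 0.0;
      for (int j = i + 1; j < n; ++j) {
        const double dx = yi0 - y0[j], dy = yi1 - y1[j];
        const double v = 1.0 / (1.0 + dx * dx + dy * dy);
        Ni[j] = v;
        num[(size_t)j * n + i] = v;
        rowsum += v;
      }
      qsum += 2.0 * rowsum;
    }
    if (qsum < 1e-300) qsum = 1e-300;
    const double inv_qsum = 1.0 / qsum;
    // Gradient: 4 * sum_j (p_ij - q_ij) num_ij (y_i - y_j).
    for (int i = 0; i < n; ++i) {
      double g0 = 0.0, g1 = 0.0;
      const double yi0 = y0[i], yi1 = y1[i];
      const double* Pi = &P[(size_t)i * n];
      const double* Ni = &num[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        const double mult = (Pi[j] - Ni[j] * inv_qsum) * Ni[j];
        g0 += mult * (yi0 - y0[j]);
        g1 += mult * (yi1 - y1[j]);
      }
      dY[(size_t)i * 2] = 4.0 * g0;
      dY[(size_t)i * 2 + 1] = 4.0 * g1;
    }
    const double momentum = (iter < theta_mom_switch) ? 0.5 : 0.8;
    double mean0 = 0.0, mean1 = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 2; ++k) {
        const size_t ik = (size_t)i * 2 + k;
        gains[ik] = ((dY[ik] > 0) != (iY[ik] > 0)) ? gains[ik] + 0.2
                                                   : gains[ik] * 0.8;
        if (gains[ik] < 0.01) gains[ik] = 0.01;
        iY[ik] = momentum * iY[ik] - eta * gains[ik] * dY[ik];
      }
      y0[i] += iY[(size_t)i * 2];
      y1[i] += iY[(size_t)i * 2 + 1];
      mean0 += y0[i];
      mean1 += y1[i];
    }
    mean0 /= n; mean1 /= n;
    for (int i = 0; i < n; ++i) { y0[i] -= mean0; y1[i] -= mean1; }
    if (iter == exaggerate_iter - 1)
      for (size_t k = 0; k < P.size(); ++k) P[k] /= exaggeration;
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix Y(n, 2);
  for (int i = 0; i < n; ++i) { Y(i, 0) = y0[i]; Y(i, 1) = y1[i]; }
  return Y;
}
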