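#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass for one observation sequence.
//
// logB: T x N matrix of per-state observation log-densities.
// A:    N x N row-stochastic transition matrix (masked entries exactly 0).
// pi:   length-N initial state distribution.
//
// Returns gamma (T x N state posteriors), xi (N x N expected transition
// counts summed over t), and the sequence log-likelihood. Row-max shifting
// of logB plus per-step scaling keeps the recursion stable for
// high-dimensional Gaussian densities.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix Bs(T, N);        // exp(logB - rowmax)
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int j = 1; j < N; ++j) if (logB(t, j) > m) m = logB(t, j);
    shift[t] = m;
    for (int j = 0; j < N; ++j) Bs(t, j) = std::exp(logB(t, j) - m);
  }

  NumericMatrix alpha(T, N), beta(T, N);
  NumericVector c(T);            // per-step scaling constants
  double ll = 0.0;

  // forward
  double s = 0.0;
  for (int j = 0; j < N; ++j) { alpha(0, j) = pi[j] * Bs(0, j); s += alpha(0, j); }
  if (s <= 0) stop("forward pass underflow at t = 0");
  c[0] = s;
  for (int j = 0; j < N; ++j) alpha(0, j) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i) acc += alpha(t - 1, i) * A(i, j);
      alpha(t, j) = acc * Bs(t, j);
      s += alpha(t, j);
    }
    if (s <= 0) stop("forward pass underflow");
    c[t] = s;
    for (int j = 0; j < N; ++j) alpha(t, j) /= s;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + shift[t];

  // backward (scaled by the forward constants)
  for (int j = 0; j < N; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      double acc = 0.0;
      for (int j = 0; j < N; ++j)
        acc += A(i, j) * Bs(t + 1, j) * beta(t + 1, j);
      beta(t, i) = acc / c[t + 1];
    }
  }

  // posteriors and expected transition counts
  NumericMatrix gamma(T, N), xi(N, N);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int j = 0; j < N; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    if (g > 0) for (int j = 0; j < N; ++j) gamma(t, j) /= g;
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < N; ++i) {
      if (alpha(t, i) == 0) continue;
      for (int j = 0; j < N; ++j) {
        if (A(i, j) == 0) continue;
        xi(i, j) += alpha(t, i) * A(i, j) * Bs(t + 1, j) * beta(t + 1, j)
          / c[t + 1];
      }
    }
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// One full EM E-pass over all sequences, batched.
//
// X:    D x Ttot pooled observations (sequences concatenated along time,
//       one column per sample so per-sample access is contiguous).
// lens: per-sequence lengths (sum = Ttot).
// mu:   N x D state means.
// Minv: (N*D) x D row-blocks; block k is the lower-triangular
//       t(solve(chol(Sigma_k))) so that quad = ||Minv_k (x - mu_k)||^2.
// logdet: per-state log-determinants of Sigma_k.
// A, pi: transition matrix and initial distribution.
//
// Returns the total log-likelihood plus the sufficient statistics needed by
// the M step: expected transition counts, state occupancies, first moments
// t(gamma) X, and raw second moments sum_t gamma_tk x_t x_t'.
// [[Rcpp::export(name = ".hmm_em_pass")]]
List hmm_em_pass(NumericMatrix X, IntegerVector lens, NumericMatrix mu,
                 NumericMatrix Minv, NumericVector logdet,
                 NumericMatrix A, NumericVector pi) {
  const int D = X.nrow(), N = mu.nrow(), S = lens.size();
  const double c2pi = D * std::log(2.0 * M_PI);
  NumericMatrix xi(N, N), mu_acc(N, D);
  NumericVector g_sum(N);
  NumericVector S_acc(N * D * D);  // [k, i, j] = k + N*(i + D*j)
  double ll_tot = 0.0;

  int maxT = 0;
  for (int s = 0; s < S; ++s) if (lens[s] > maxT) maxT = lens[s];
  std::vector<double> logB(maxT * N), Bs(maxT * N), alpha(maxT * N),
    beta(maxT * N), cvec(maxT), shift(maxT), v(D);

  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    // per-state Gaussian log-densities
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < N; ++k) {
        double quad = 0.0;
        for (int i = 0; i < D; ++i) v[i] = X(i, off + t) - mu(k, i);
        for (int i = 0; i < D; ++i) {
          double acc = 0.0;
          for (int j = 0; j <= i; ++j) acc += Minv(k * D + i, j) * v[j];
          quad += acc * acc;
        }
        logB[t * N + k] = -0.5 * (c2pi + logdet[k] + quad);
      }
      double m = logB[t * N];
      for (int k = 1; k < N; ++k) if (logB[t * N + k] > m) m = logB[t * N + k];
      shift[t] = m;
      for (int k = 0; k < N; ++k) Bs[t * N + k] = std::exp(logB[t * N + k] - m);
    }
    // scaled forward
    double ssum = 0.0;
    for (int k = 0; k < N; ++k) { alpha[k] = pi[k] * Bs[k]; ssum += alpha[k]; }
    if (ssum <= 0) stop("forward pass underflow at t = 0");
    cvec[0] = ssum;
    for (int k = 0; k < N; ++k) alpha[k] /= ssum;
    for (int t = 1; t < T; ++t) {
      ssum = 0.0;
      for (int j = 0; j < N; ++j) {
        double acc = 0.0;
        for (int i = 0; i < N; ++i) acc += alpha[(t - 1) * N + i] * A(i, j);
        alpha[t * N + j] = acc * Bs[t * N + j];
        ssum += alpha[t * N + j];
      }
      if (ssum <= 0) stop("forward pass underflow");
      cvec[t] = ssum;
      for (int j = 0; j < N; ++j) alpha[t * N + j] /= ssum;
    }
    for (int t = 0; t < T; ++t) ll_tot += std::log(cvec[t]) + shift[t];
    // scaled backward + accumulation
    for (int k = 0; k < N; ++k) beta[(T - 1) * N + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j)
          acc += A(i, j) * Bs[(t + 1) * N + j] * beta[(t + 1) * N + j];
        beta[t * N + i] = acc / cvec[t + 1];
      }
    }
    for (int t = 0; t < T; ++t) {
      double gnorm = 0.0;
      for (int k = 0; k < N; ++k) gnorm += alpha[t * N + k] * beta[t * N + k];
      if (gnorm <= 0) continue;
      for (int k = 0; k < N; ++k) {
        double gk = alpha[t * N + k] * beta[t * N + k] / gnorm;
        if (gk == 0) continue;
        g_sum[k] += gk;
        for (int i = 0; i < D; ++i) {
          const double xi_val = X(i, off + t);
          mu_acc(k, i) += gk * xi_val;
          double *srow = &S_acc[k + N * i];
          for (int j = i; j < D; ++j)
            srow[N * D * j] += gk * xi_val * X(j, off + t);
        }
      }
      if (t + 1 < T) {
        for (int i = 0; i < N; ++i) {
          if (alpha[t * N + i] == 0) continue;
          for (int j = 0; j < N; ++j) {
            if (A(i, j) == 0) continue;
            xi(i, j) += alpha[t * N + i] * A(i, j) * Bs[(t + 1) * N + j] *
              beta[(t + 1) * N + j] / cvec[t + 1];
          }
        }
      }
    }
    off += T;
  }
  S_acc.attr("dim") = IntegerVector::create(N, D, D);
  return List::create(_["loglik"] = ll_tot, _["xi"] = xi,
                      _["g_sum"] = g_sum, _["mu_acc"] = mu_acc,
                      _["S_acc"] = S_acc);
}
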