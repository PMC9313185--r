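#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward (Rabiner normalisation) over one sequence.
// logB: T x K emission log-densities; pi: length K; A: K x K row-stochastic.
// Hot loops run on raw row-major buffers; R matrices are column-major, so
// logB/gamma are indexed t + k*T while scratch uses t*K + k.
// Returns gamma (T x K), xi_sum (K x K expected transition counts), loglik.
// [[Rcpp::export]]
List fb_core(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), K = logB.ncol();
  const double* lb = REAL(logB);
  const double* pp = REAL(pi);
  std::vector<double> B((size_t)T * K), al((size_t)T * K), be((size_t)T * K),
      c(T), mx(T), Arm((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Arm[i * K + j] = A(i, j);

  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double v = lb[t + (size_t)k * T];
      if (v > m) m = v;
    }
    if (!R_finite(m))
      stop("all emission log-likelihoods are -Inf at time %d", t + 1);
    mx[t] = m;
    for (int k = 0; k < K; ++k)
      B[(size_t)t * K + k] = std::exp(lb[t + (size_t)k * T] - m);
  }

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { al[k] = pp[k] * B[k]; s += al[k]; }
  if (s <= 0.0) stop("forward pass underflow at time 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) al[k] /= s;
  for (int t = 1; t < T; ++t) {
    const double* ap = &al[(size_t)(t - 1) * K];
    double* an = &al[(size_t)t * K];
    const double* bt = &B[(size_t)t * K];
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += ap[j] * Arm[j * K + k];
      a *= bt[k];
      an[k] = a;
      s += a;
    }
    if (s <= 0.0) stop("forward pass underflow at time %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) an[k] /= s;
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + mx[t];

  // backward
  for (int k = 0; k < K; ++k) be[(size_t)(T - 1) * K + k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double* bn = &be[(size_t)(t + 1) * K];
    const double* Bt1 = &B[(size_t)(t + 1) * K];
    double* bt = &be[(size_t)t * K];
    const double ci = 1.0 / c[t + 1];
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += Arm[i * K + j] * Bt1[j] * bn[j];
      bt[i] = b * ci;
    }
  }

  NumericMatrix gamma(T, K), xi(K, K);
  double* gp = REAL(gamma);
  double* xp = REAL(xi);
  for (int t = 0; t < T; ++t) {
    const double* at = &al[(size_t)t * K];
    const double* bt = &be[(size_t)t * K];
    double g = 0.0;
    for (int k = 0; k < K; ++k) g += at[k] * bt[k];
    for (int k = 0; k < K; ++k) gp[t + (size_t)k * T] = at[k] * bt[k] / g;
  }
  for (int t = 0; t < T - 1; ++t) {
    const double* at = &al[(size_t)t * K];
    const double* bn = &be[(size_t)(t + 1) * K];
    const double* Bt1 = &B[(size_t)(t + 1) * K];
    const double ci = 1.0 / c[t + 1];
    for (int i = 0; i < K; ++i) {
      double ai = at[i] * ci;
      for (int j = 0; j < K; ++j)
        xp[i + j * K] += ai * Arm[i * K + j] * Bt1[j] * bn[j];
    }
  }

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// [[Rcpp::export]]
List viterbi_core(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), K = logB.ncol();
  const double* lb = REAL(logB);
  std::vector<double> delta((size_t)T * K), logA((size_t)K * K);
  std::vector<int> psi((size_t)T * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) logA[i * K + j] = std::log(A(i, j));
  for (int k = 0; k < K; ++k)
    delta[k] = std::log(pi[k]) + lb[(size_t)k * T];
  for (int t = 1; t < T; ++t) {
    const double* dp = &delta[(size_t)(t - 1) * K];
    double* dn = &delta[(size_t)t * K];
    int* pn = &psi[(size_t)t * K];
    for (int k = 0; k < K; ++k) {
      double best = dp[0] + logA[k];
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = dp[j] + logA[j * K + k];
        if (v > best) { best = v; arg = j; }  // strict: lowest index wins ties
      }
      dn[k] = best + lb[t + (size_t)k * T];
      pn[k] = arg;
    }
  }
  const double* dl = &delta[(size_t)(T - 1) * K];
  double best = dl[0];
  int arg = 0;
  for (int k = 1; k < K; ++k) if (dl[k] > best) { best = dl[k]; arg = k; }
  if (!R_finite(best)) stop("no admissible state path (all path scores -Inf)");
  IntegerVector path(T);
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + (path[t + 1] - 1)] + 1;
  return List::create(_["path"] = path, _["logscore"] = best);
}

// Time-inhomogeneous Markov chain sampler. Uses pre-drawn uniforms so the
// RNG stream stays under R's control. A_pre applies while the destination
// sample index (0-based) is < split_idx, A_post afterwards.
// [[Rcpp::export]]
IntegerVector sample_chain_core(NumericVector pi, NumericMatrix A_pre,
                                NumericMatrix A_post, int split_idx,
                                NumericVector u) {
  const int T = u.size(), K = pi.size();
  IntegerVector s(T);
  double acc = 0.0;
  int st = K - 1;
  for (int k = 0; k < K; ++k) { acc += pi[k]; if (u[0] <= acc) { st = k; break; } }
  s[0] = st + 1;
  for (int t = 1; t < T; ++t) {
    const NumericMatrix& A = (t < split_idx) ? A_pre : A_post;
    acc = 0.0;
    int nx = K - 1;
    for (int k = 0; k < K; ++k) { acc += A(st, k); if (u[t] <= acc) { nx = k; break; } }
    st = nx;
    s[t] = st + 1;
  }
  return s;
}
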