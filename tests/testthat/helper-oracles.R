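# Brute-force oracles: exhaustive path enumeration for forward-backward
# and Viterbi on tiny problems. Independent of the package's recursions.

enumerate_paths <- function(T, K) as.matrix(expand.grid(rep(list(seq_len(K)), T)))

enum_posteriors <- function(logB, pi, A) {
  T <- nrow(logB)
  K <- ncol(logB)
  paths <- enumerate_paths(T, K)
  logp <- apply(paths, 1, function(s) {
    lp <- log(pi[s[1]]) + logB[1, s[1]]
    if (T > 1) for (t in 2:T) lp <- lp + log(A[s[t - 1], s[t]]) + logB[t, s[t]]
    lp
  })
  m <- max(logp)
  loglik <- m + log(sum(exp(logp - m)))
  w <- exp(logp - loglik)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k])
  xi <- matrix(0, K, K)
  if (T > 1) for (t in seq_len(T - 1))
    for (i in seq_len(K)) for (j in seq_len(K))
      xi[i, j] <- xi[i, j] + sum(w[paths[, t] == i & paths[, t + 1] == j])
  list(loglik = loglik, gamma = gamma, xi_sum = xi,
       best_logscore = max(logp))
}

# Random valid HMM parameters for oracle comparisons.
random_hmm <- function(K, M, seed) {
  set.seed(seed)
  pi <- rdirichlet_vec(rep(1, K))
  A <- t(vapply(seq_len(K), function(i) rdirichlet_vec(rep(1, K)), numeric(K)))
  mu <- matrix(rnorm(K * M, sd = 2), K, M)
  Sigma <- array(0, c(K, M, M))
  for (k in seq_len(K)) {
    W <- matrix(rnorm(M * (M + 2)), M)
    Sigma[k, , ] <- tcrossprod(W) / (M + 2) + 0.1 * diag(M)
  }
  hmm_params(pi, A, mu, Sigma)
}

rdirichlet_vec <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

# Direct multivariate normal log-density with an explicit inverse.
dmvnorm_log_direct <- function(y, mu, Sigma) {
  M <- length(mu)
  d <- y - mu
  -0.5 * (M * log(2 * pi) + log(det(Sigma)) +
            as.numeric(t(d) %*% solve(Sigma) %*% d))
}
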