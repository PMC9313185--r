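test_that("emission log-densities match closed forms", {
  # standard normal at its mean
  p1 <- hmm_params(1, matrix(1, 1, 1), matrix(0, 1, 1), array(1, c(1, 1, 1)))
  expect_equal(emission_loglik(matrix(0, 1, 1), p1)[1, 1], -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # diagonal covariance factorises into univariate terms
  mu <- c(1, -2)
  v <- c(4, 0.25)
  p2 <- hmm_params(1, matrix(1, 1, 1), matrix(mu, 1, 2),
                   array(diag(v), c(1, 2, 2)))
  y <- c(0.5, -1)
  expect_equal(emission_loglik(matrix(y, 2, 1), p2)[1, 1],
               sum(dnorm(y, mu, sqrt(v), log = TRUE)), tolerance = 1e-12)
  # full covariance matches a direct inverse-based evaluation
  set.seed(1)
  par <- random_hmm(2, 3, seed = 1)
  Y <- matrix(rnorm(15), 3, 5)
  ll <- emission_loglik(Y, par)
  for (t in 1:5) for (k in 1:2)
    expect_equal(ll[t, k],
                 dmvnorm_log_direct(Y[, t], par$mu[k, ], par$Sigma[k, , ]),
                 tolerance = 1e-10)
})

test_that("forward-backward matches exhaustive enumeration", {
  for (seed in 1:10) {
    K <- sample(2:3, 1)
    T <- sample(2:5, 1)
    par <- random_hmm(K, 2, seed = seed)
    set.seed(seed + 100)
    logB <- matrix(rnorm(T * K), T, K)
    fb <- forward_backward(logB, par$pi, par$A)
    oracle <- enum_posteriors(logB, par$pi, par$A)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
    expect_equal(fb$xi_sum, oracle$xi_sum, tolerance = 1e-10)
  }
})

test_that("single-state and absorbing chains give trivial posteriors", {
  logB <- matrix(rnorm(20), 20, 1)
  fb <- forward_backward(logB, 1, matrix(1, 1, 1))
  expect_true(all(fb$gamma == 1))
  expect_equal(fb$loglik, sum(logB), tolerance = 1e-12)
  expect_equal(viterbi(logB, 1, matrix(1, 1, 1))$path, rep(1L, 20))
  # absorbing two-state chain started in state 1
  logB2 <- matrix(rnorm(30), 15, 2)
  fb2 <- forward_backward(logB2, c(1, 0), diag(2))
  expect_equal(fb2$gamma[, 1], rep(1, 15), tolerance = 1e-12)
})

test_that("viterbi achieves the enumerated maximum path score", {
  for (seed in 1:20) {
    par <- random_hmm(3, 2, seed = seed + 500)
    set.seed(seed + 600)
    logB <- matrix(rnorm(6 * 3), 6, 3)
    v <- viterbi(logB, par$pi, par$A)
    oracle <- enum_posteriors(logB, par$pi, par$A)
    expect_equal(v$logscore, oracle$best_logscore, tolerance = 1e-10)
  }
})

test_that("viterbi recovers well-separated generating paths", {
  par <- hmm_params(c(0.5, 0.5), matrix(c(0.95, 0.05, 0.05, 0.95), 2),
                    matrix(c(-10, 10), 2, 1), array(1, c(2, 1, 1)))
  set.seed(7)
  path <- erpstates:::sample_chain_core(par$pi, par$A, par$A, 1L, runif(400))
  Y <- matrix(rnorm(400, mean = par$mu[path, 1]), 1, 400)
  v <- viterbi(emission_loglik(Y, par), par$pi, par$A)
  expect_equal(v$path, path)
})

test_that("K = 1 EM reduces to the pooled Gaussian closed form", {
  set.seed(9)
  obs <- list(matrix(rnorm(200, sd = 2), 2, 100),
              matrix(rnorm(160, sd = 2), 2, 80))
  fit <- fit_hmm(obs, K = 1, n_restarts = 1, seed = 1, ridge = 1e-6)
  X <- cbind(obs[[1]], obs[[2]])
  mu <- rowMeans(X)
  S <- tcrossprod(X - mu) / ncol(X)           # ML denominator T
  S_ridged <- S + 1e-6 * mean(diag(S)) * diag(2)
  expect_equal(as.vector(fit$params$mu), mu, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$params$Sigma[1, , ], S_ridged, tolerance = 1e-8)
})

test_that("EM increases the likelihood and pools responsibilities coherently", {
  set.seed(11)
  tr <- build_ground_truth(K = 3, M = 3, seed = 11)
  obs <- lapply(1:3, function(i) {
    p <- sample_state_sequence(tr, "comfort", 150, fs = 512, seed = 20 + i)
    sample_emissions(tr, p, seed = 30 + i)
  })
  fit <- fit_hmm(obs, K = 3, n_restarts = 3, seed = 5, max_iter = 100)
  tr_ll <- fit$loglik_trace
  expect_true(all(diff(tr_ll) >= -1e-7 * abs(tr_ll[-length(tr_ll)])))
  # gamma rows sum to 1; pooled transition counts = total transitions
  for (g in fit$posteriors$gamma)
    expect_equal(rowSums(g), rep(1, nrow(g)), tolerance = 1e-10)
  expect_equal(sum(fit$posteriors$xi_sum), sum(vapply(obs, ncol, 0L)) - 3,
               tolerance = 1e-8)
  expect_equal(rowSums(fit$params$A), rep(1, 3), tolerance = 1e-10)
})

test_that("EM is equivariant under permutation of the initialisation", {
  set.seed(13)
  tr <- build_ground_truth(K = 3, M = 2, seed = 13)
  p <- sample_state_sequence(tr, "comfort", 400, fs = 512, seed = 1)
  Y <- sample_emissions(tr, p, seed = 2)
  init <- hmm_params(tr$pi, tr$A, tr$mu, tr$Sigma)
  fit1 <- fit_hmm(Y, K = 3, init = init, max_iter = 40)
  perm <- c(3, 1, 2)
  init_p <- hmm_params(init$pi[perm], init$A[perm, perm],
                       init$mu[perm, , drop = FALSE],
                       init$Sigma[perm, , , drop = FALSE])
  fit2 <- fit_hmm(Y, K = 3, init = init_p, max_iter = 40)
  expect_equal(fit2$params$mu, fit1$params$mu[perm, ], tolerance = 1e-6)
  expect_equal(fit2$params$A, fit1$params$A[perm, perm], tolerance = 1e-6)
  expect_equal(fit2$posteriors$loglik, fit1$posteriors$loglik,
               tolerance = 1e-8)
})

test_that("fc_matrix returns covariance or unit-diagonal correlation", {
  S <- matrix(c(4, 2, 2, 1.5), 2)
  par <- hmm_params(c(1, 0), diag(2), matrix(0, 2, 2),
                    array(rbind(S, S), c(2, 2, 2)))
  par$Sigma[1, , ] <- S
  par$Sigma[2, , ] <- diag(2)
  expect_equal(fc_matrix(par, 1, "covariance"), S)
  R <- fc_matrix(par, 1, "correlation")
  expect_equal(diag(R), c(1, 1), tolerance = 1e-12)
  expect_equal(R[1, 2], 2 / sqrt(4 * 1.5), tolerance = 1e-12)
  expect_error(fc_matrix(par, 5), "out of range")
})

test_that("fit input validation guards shapes and sizes", {
  expect_error(fit_hmm(list(matrix(0, 2, 5), matrix(0, 3, 5)), K = 2),
               "share the channel count")
  expect_error(fit_hmm(matrix(rnorm(10), 2, 5), K = 2), "too few samples")
})
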