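# Maximum-likelihood hidden Markov model with multivariate Gaussian
# emissions. The state covariance is read as the functional-connectivity
# pattern between channels; fitting is Baum-Welch EM with multi-restart
# selection by final log-likelihood, decoding is Viterbi.

#' Gaussian-emission HMM parameter set
#'
#' @param pi initial state distribution (length K, sums to 1).
#' @param A K x K row-stochastic transition matrix.
#' @param mu K x M matrix of state mean vectors.
#' @param Sigma K x M x M array of state covariance matrices (symmetric,
#'   positive definite).
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, mu, Sigma) {
  K <- length(pi)
  M <- ncol(mu)
  stopifnot(nrow(A) == K, ncol(A) == K, nrow(mu) == K,
            all(dim(Sigma) == c(K, M, M)))
  if (abs(sum(pi) - 1) > 1e-10) stop("pi must sum to 1", call. = FALSE)
  if (any(abs(rowSums(A) - 1) > 1e-10))
    stop("A rows must sum to 1", call. = FALSE)
  structure(list(K = as.integer(K), M = as.integer(M), pi = pi, A = A,
                 mu = mu, Sigma = Sigma),
            class = "hmm_params")
}

#' Per-state Gaussian emission log-densities
#'
#' Entry (t, k) is `log N(Y[, t]; mu[k, ], Sigma[k, , ])`, evaluated through
#' the Cholesky factor of each state covariance.
#'
#' @param Y M x T observation matrix (channels x time).
#' @param params an `hmm_params`.
#' @return T x K matrix of log-densities (nats).
#' @export
emission_loglik <- function(Y, params) {
  if (nrow(Y) != params$M)
    stop("observation channel count does not match params$M", call. = FALSE)
  T <- ncol(Y)
  out <- matrix(0, T, params$K)
  for (k in seq_len(params$K)) {
    L <- tryCatch(chol(params$Sigma[k, , ]), error = function(e)
      stop("covariance of state ", k, " is not positive definite: ",
           conditionMessage(e), call. = FALSE))
    X <- Y - params$mu[k, ]
    Z <- backsolve(L, X, transpose = TRUE)       # solve L' Z = X
    out[, k] <- -0.5 * (params$M * log(2 * pi) + colSums(Z^2)) -
      sum(log(diag(L)))
  }
  out
}

#' Forward-backward posterior inference for one sequence
#'
#' Scaled recursions (per-step normalisation), so sequences up to ~1e5
#' samples do not underflow.
#'
#' @param logB T x K matrix of emission log-likelihoods.
#' @param pi initial distribution; `A` transition matrix.
#' @param A K x K transition matrix.
#' @return list with `gamma` (T x K posterior state probabilities; rows sum
#'   to 1), `xi_sum` (K x K expected transition counts) and `loglik`
#'   (log P(Y), nats).
#' @export
forward_backward <- function(logB, pi, A) {
  stopifnot(ncol(logB) == length(pi), all(dim(A) == length(pi)))
  fb_core(logB, pi, A)
}

#' Viterbi decoding
#'
#' Maximum-a-posteriori joint state path; ties at any argmax step are
#' broken toward the lower state index, making the decoding deterministic.
#'
#' @inheritParams forward_backward
#' @return list with `path` (integer states 1..K) and `logscore` (the
#'   path's joint log-probability).
#' @export
viterbi <- function(logB, pi, A) {
  stopifnot(ncol(logB) == length(pi), all(dim(A) == length(pi)))
  viterbi_core(logB, pi, A)
}

#' Z-score each channel of a sequence
#'
#' @param Y M x T matrix.
#' @return Y with each row centred and scaled to unit standard deviation
#'   (constant rows are only centred).
#' @export
standardize_channels <- function(Y) {
  m <- rowMeans(Y)
  s <- apply(Y, 1, sd)
  s[s == 0] <- 1
  (Y - m) / s
}

# One M-step from pooled responsibilities. X is M x Ttot.
mstep_gauss <- function(X, gamma, ridge) {
  K <- ncol(gamma)
  M <- nrow(X)
  Nk <- colSums(gamma)
  mu <- matrix(0, K, M)
  Sigma <- array(0, c(K, M, M))
  for (k in seq_len(K)) {
    Xw <- X * rep(gamma[, k], each = M)
    mu[k, ] <- rowSums(Xw) / Nk[k]
    S <- tcrossprod(Xw, X) / Nk[k] - tcrossprod(mu[k, ])
    S <- (S + t(S)) / 2
    Sigma[k, , ] <- S + ridge * mean(diag(S)) * diag(M)
  }
  list(mu = mu, Sigma = Sigma, Nk = Nk)
}

#' Fit a Gaussian-emission HMM by multi-restart EM
#'
#' Baum-Welch with shared parameters across sequences: the E-step runs
#' forward-backward per sequence (each sequence restarts from `pi`, so no
#' spurious transition is created at subject boundaries), the M-step pools
#' responsibilities across sequences. Each restart starts from random
#' responsibilities; the restart with the highest final log-likelihood wins
#' (the maximum-likelihood analogue of minimum free energy). Covariance
#' updates carry a `ridge * mean-diagonal` regulariser.
#'
#' A state whose total responsibility falls below one sample-equivalent is
#' reinitialised once within its restart; if it collapses again the restart
#' is abandoned with a warning.
#'
#' @param obs list of M x T_j observation matrices (or a single matrix).
#' @param K number of states.
#' @param n_restarts number of EM restarts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @param seed integer; restart r uses seed + r - 1.
#' @param ridge covariance regularisation factor.
#' @param init optional `hmm_params` used as the starting point of a single
#'   EM run (overrides `n_restarts`).
#' @return list of class `hmm_fit`: `params`, `posteriors` (per-sequence
#'   gamma, pooled `xi_sum`, `loglik`), `paths` (per-sequence Viterbi
#'   paths), `loglik_trace`, `restart_index`, `restart_logliks`,
#'   `seed_used`.
#' @export
fit_hmm <- function(obs, K, n_restarts = 20, tol = 1e-6, max_iter = 500,
                    seed = 1L, ridge = 1e-6, init = NULL) {
  if (is.matrix(obs)) obs <- list(obs)
  stopifnot(length(obs) >= 1, is_count(K, 1))
  M <- nrow(obs[[1]])
  if (any(vapply(obs, nrow, 0L) != M))
    stop("all sequences must share the channel count", call. = FALSE)
  if (any(vapply(obs, ncol, 0L) < 2))
    stop("each sequence needs at least 2 samples", call. = FALSE)
  Tj <- vapply(obs, ncol, 0L)
  Ttot <- sum(Tj)
  if (Ttot < 10 * K * M)
    stop("too few samples for a ", K, "-state, ", M,
         "-channel fit (need >= 10*K*M = ", 10 * K * M, ")", call. = FALSE)
  X <- do.call(cbind, obs)
  ends <- cumsum(Tj)
  starts <- c(1L, head(ends, -1L) + 1L)

  run_restart <- function(r) {
    params <- if (!is.null(init)) init else with_seed(seed + r - 1L, {
      g0 <- matrix(rexp(Ttot * K), Ttot, K)
      g0 <- g0 / rowSums(g0)
      ms <- mstep_gauss(X, g0, ridge)
      A0 <- normalize_rows(matrix(runif(K * K), K, K) + K * diag(K))
      hmm_params(rep(1 / K, K), A0, ms$mu, ms$Sigma)
    })
    trace <- numeric(0)
    reinit_used <- FALSE
    for (iter in seq_len(max_iter)) {
      logB <- emission_loglik(X, params)
      gamma <- matrix(0, Ttot, K)
      xi <- matrix(0, K, K)
      pi_acc <- numeric(K)
      ll <- 0
      for (j in seq_along(obs)) {
        rows <- starts[j]:ends[j]
        fb <- fb_core(logB[rows, , drop = FALSE], params$pi, params$A)
        gamma[rows, ] <- fb$gamma
        xi <- xi + fb$xi_sum
        pi_acc <- pi_acc + fb$gamma[1, ]
        ll <- ll + fb$loglik
      }
      trace <- c(trace, ll)
      Nk <- colSums(gamma)
      if (any(Nk < 1)) {
        if (reinit_used) {
          warning("restart ", r, ": state collapsed twice; abandoning",
                  call. = FALSE)
          return(NULL)
        }
        reinit_used <- TRUE
        for (k in which(Nk < 1)) {
          params$mu[k, ] <- X[, sample.int(Ttot, 1)]
          S <- tcrossprod(X - rowMeans(X)) / Ttot
          params$Sigma[k, , ] <- S + ridge * mean(diag(S)) * diag(M)
        }
        next
      }
      ms <- mstep_gauss(X, gamma, ridge)
      params$mu <- ms$mu
      params$Sigma <- ms$Sigma
      params$A <- normalize_rows(xi)
      params$pi <- pi_acc / length(obs)
      if (iter > 1) {
        prev <- trace[length(trace) - 1]
        if (abs(ll - prev) / max(abs(prev), 1e-12) < tol) break
      }
    }
    list(params = params, loglik = trace[length(trace)], trace = trace)
  }

  if (!is.null(init)) n_restarts <- 1L
  fits <- lapply(seq_len(n_restarts), run_restart)
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else f$loglik, 0)
  if (all(!is.finite(lls)))
    stop("all EM restarts failed (state collapse)", call. = FALSE)
  win <- which.max(lls)
  best <- fits[[win]]
  params <- best$params

  # final E-step so posteriors and decoded paths match the final parameters
  logB <- emission_loglik(X, params)
  gamma_seq <- vector("list", length(obs))
  xi <- matrix(0, K, K)
  ll <- 0
  paths <- vector("list", length(obs))
  for (j in seq_along(obs)) {
    rows <- starts[j]:ends[j]
    fb <- fb_core(logB[rows, , drop = FALSE], params$pi, params$A)
    gamma_seq[[j]] <- fb$gamma
    xi <- xi + fb$xi_sum
    ll <- ll + fb$loglik
    paths[[j]] <- viterbi_core(logB[rows, , drop = FALSE], params$pi,
                               params$A)$path
  }
  names(gamma_seq) <- names(paths) <- names(obs)

  structure(list(params = params,
                 posteriors = list(gamma = gamma_seq, xi_sum = xi, loglik = ll),
                 paths = paths,
                 loglik_trace = best$trace,
                 restart_index = win,
                 restart_logliks = lls,
                 seed_used = as.integer(seed)),
            class = "hmm_fit")
}

#' Functional-connectivity matrix of a state
#'
#' The state covariance is the state's functional-connectivity pattern
#' between channels; `kind = "correlation"` rescales it to a correlation
#' matrix.
#'
#' @param params an `hmm_params` (or an `hmm_fit`, whose params are used).
#' @param k state index.
#' @param kind "covariance" or "correlation".
#' @return M x M matrix.
#' @export
fc_matrix <- function(params, k, kind = c("covariance", "correlation")) {
  if (inherits(params, "hmm_fit")) params <- params$params
  kind <- match.arg(kind)
  if (k < 1 || k > params$K) stop("state index out of range", call. = FALSE)
  S <- matrix(params$Sigma[k, , ], params$M, params$M)
  if (kind == "covariance") return(S)
  v <- diag(S)
  if (any(v <= 0))
    stop("zero variance on a channel; correlation is degenerate", call. = FALSE)
  R <- S / sqrt(outer(v, v))
  diag(R) <- 1
  R
}
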