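# Synthetic two-condition ERP study generator with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes, not EEG physiology: a hidden K-state Markov chain with
# state-specific channel covariances (the "connectivity patterns"), a
# condition-dependent bias toward the weak-connectivity state after a split
# time, and an additive ERP component-window effect on a channel subset in
# one condition.

#' Configuration for a synthetic ERP study
#'
#' Holds the acquisition-level settings of a simulated two-condition,
#' multi-subject EEG experiment: epoch geometry, sampling rate, trial count
#' and noise, plus the seed making the study reproducible.
#'
#' @param n_subjects number of subjects (each contributes both conditions).
#' @param n_trials trials per subject and condition.
#' @param fs sampling rate in Hz.
#' @param epoch_start_ms,epoch_end_ms epoch bounds relative to stimulus
#'   onset in ms; the pre-onset part is the baseline.
#' @param split_ms boundary between the early and late period (ms
#'   post-onset); early is `<= split_ms`.
#' @param noise_sd standard deviation of the white per-trial noise added to
#'   the subject's ERP template (signal units).
#' @param subject_jitter Dirichlet concentration used to perturb each
#'   subject's transition-matrix rows around the group matrix; larger means
#'   less between-subject variability.
#' @param smooth_len length (samples) of the moving average applied to the
#'   raw state-conditional draws; raw white draws are unrealistically rough
#'   for ERP-like signals.
#' @param seed integer seed governing every random draw of the study.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 37, n_trials = 40, fs = 512,
                         epoch_start_ms = -200, epoch_end_ms = 3000,
                         split_ms = 1100, noise_sd = 1, subject_jitter = 200,
                         smooth_len = 5, seed = 1L) {
  if (!is_count(n_subjects, 2)) stop("n_subjects must be an integer >= 2", call. = FALSE)
  if (!is_count(n_trials, 1)) stop("n_trials must be an integer >= 1", call. = FALSE)
  if (!(epoch_start_ms < 0 && 0 < split_ms && split_ms < epoch_end_ms))
    stop("need epoch_start_ms < 0 < split_ms < epoch_end_ms", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), fs = fs,
                 epoch_start_ms = epoch_start_ms, epoch_end_ms = epoch_end_ms,
                 split_ms = split_ms, noise_sd = noise_sd,
                 subject_jitter = subject_jitter,
                 smooth_len = as.integer(smooth_len), seed = as.integer(seed)),
            class = "synth_config")
}

#' Synthetic scalp montage
#'
#' Channel labels with a four-region scalp map (frontal, temporal, parietal,
#' occipital), channels split as evenly as possible across regions.
#'
#' @param M number of channels.
#' @return list with `channels` (labels) and `regions` (named character
#'   vector channel -> region).
#' @export
synthetic_montage <- function(M) {
  if (!is_count(M, 2)) stop("M must be an integer >= 2", call. = FALSE)
  reg <- c("F", "T", "P", "O")
  sizes <- diff(floor(seq(0, M, length.out = 5)))
  region <- rep(reg, times = sizes)
  labels <- unlist(lapply(reg, function(r) {
    n <- sum(region == r)
    if (n) paste0(r, seq_len(n)) else character(0)
  }))
  list(channels = labels, regions = stats::setNames(region, labels))
}

#' Build a ground-truth state model for simulation
#'
#' Constructs the hidden-Markov ground truth of a synthetic study: a sticky
#' K-state chain, per-state mean vectors, and per-state covariance matrices
#' in which one state has near-diagonal ("weak connectivity") structure and
#' one has strong positive off-diagonal correlations. Covariances are
#' rebuilt from their eigendecomposition as `Q diag(lambda) Q' + eps I` with
#' `eps = 1e-6 * mean(lambda)`, guaranteeing positive definiteness.
#'
#' @param K number of states (>= 2).
#' @param M number of channels (>= 2).
#' @param seed integer seed; construction is deterministic given it.
#' @param stickiness diagonal of the baseline transition matrix.
#' @param mu_sd standard deviation of the state-mean entries (signal units).
#'   State identity is carried primarily by the covariance (connectivity)
#'   structure; the means add moderate extra separation.
#' @param weak_mix,mid_mix,strong_base mixing weights shaping the weak,
#'   intermediate and strong correlation structures.
#' @param late_bias named per-condition multiplicative bias (>= 1) applied
#'   to the weak-state transition column after the split time.
#' @param early_bias bias toward the strong state before the split time.
#' @param component_effect list describing the ERP component effect:
#'   `channels` (labels or indices; NULL = the frontal-temporal half of the
#'   synthetic montage), `window_ms` (length-2), `shift` (signal units) and
#'   `condition` receiving the shift.
#' @return list of class `ground_truth_model`.
#' @export
build_ground_truth <- function(K = 4, M = 8, seed = 1L, stickiness = 0.9,
                               mu_sd = 1, weak_mix = 0.05, mid_mix = 0.45,
                               strong_base = 0.65,
                               late_bias = c(comfort = 1, discomfort = 2.5),
                               early_bias = 2,
                               component_effect = list(channels = NULL,
                                                       window_ms = c(90, 130),
                                                       shift = 2,
                                                       condition = "discomfort")) {
  if (!is_count(K, 2)) stop("K must be an integer >= 2", call. = FALSE)
  if (!is_count(M, 2)) stop("M must be an integer >= 2", call. = FALSE)
  if (any(late_bias < 1)) stop("late_bias entries must be >= 1", call. = FALSE)
  montage <- synthetic_montage(M)
  weak_state <- K                      # highest-indexed state is the weak one
  strong_state <- min(2L, K - 1L)
  # default effect support: the frontal-temporal half of the montage,
  # mirroring a frontally dominated component effect spanning a sizeable
  # fraction of the electrodes
  if (is.null(component_effect$channels))
    component_effect$channels <- montage$channels[seq_len(ceiling(M / 2))]

  with_seed(seed, {
    pi <- rep(1 / K, K)
    A <- matrix((1 - stickiness) / (K - 1), K, K)
    diag(A) <- stickiness
    mu <- matrix(rnorm(K * M, sd = mu_sd), K, M)
    Sigma <- array(0, c(K, M, M))
    for (k in seq_len(K)) {
      W <- matrix(rnorm(M * M), M)
      R0 <- stats::cov2cor(tcrossprod(W) + 0.5 * diag(M))
      R <- if (k == weak_state) {
        weak_mix * R0 + (1 - weak_mix) * diag(M)
      } else if (k == strong_state) {
        # strong positive coupling through a heterogeneous one-factor
        # loading (not a pure common mode, which average rereferencing
        # would remove entirely)
        u <- runif(M, 0.6, 1.4)
        L <- sqrt(strong_base) * u / mean(u)
        Rs <- tcrossprod(L)
        diag(Rs) <- 1
        Rs
      } else {
        mid_mix * R0 + (1 - mid_mix) * diag(M)
      }
      v <- runif(M, 0.6, 1.4)
      S <- diag(sqrt(v)) %*% R %*% diag(sqrt(v))
      e <- eigen((S + t(S)) / 2, symmetric = TRUE)
      lam <- pmax(e$values, 0)
      Sigma[k, , ] <- e$vectors %*% (lam * t(e$vectors)) +
        1e-6 * mean(lam) * diag(M)
    }
    structure(list(K = as.integer(K), M = as.integer(M), pi = pi, A = A,
                   mu = mu, Sigma = Sigma, weak_state = weak_state,
                   strong_state = strong_state, late_bias = late_bias,
                   early_bias = early_bias,
                   component_effect = component_effect,
                   channels = montage$channels, regions = montage$regions,
                   seed = as.integer(seed)),
              class = "ground_truth_model")
  })
}

# Index of the last sample (1-based, post-onset grid) in the early period.
split_index <- function(split_ms, fs, T) min(floor(split_ms * fs / 1000) + 1L, T)

#' Sample a ground-truth state sequence
#'
#' Draws a time-inhomogeneous Markov chain of length `T`: before the split
#' time the strong-state transition column is upweighted by `early_bias`,
#' after it the weak-state column by `late_bias[condition]` (rows
#' renormalised), mimicking early engagement followed by condition-dependent
#' disengagement.
#'
#' @param truth a `ground_truth_model`.
#' @param condition condition label; must name an entry of
#'   `truth$late_bias`.
#' @param T sequence length (samples, post-onset grid starting at 0 ms).
#' @param fs sampling rate (Hz).
#' @param split_ms early/late boundary (ms); early is `<= split_ms`.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return integer vector of states in 1..K.
#' @export
sample_state_sequence <- function(truth, condition, T, fs = 512,
                                  split_ms = 1100, seed = NULL) {
  if (!is_count(T, 1)) stop("T must be a positive integer", call. = FALSE)
  if (!condition %in% names(truth$late_bias))
    stop("unknown condition label: ", condition, call. = FALSE)
  A_pre <- truth$A
  A_pre[, truth$strong_state] <- A_pre[, truth$strong_state] * truth$early_bias
  A_pre <- normalize_rows(A_pre)
  A_post <- truth$A
  A_post[, truth$weak_state] <-
    A_post[, truth$weak_state] * truth$late_bias[[condition]]
  A_post <- normalize_rows(A_post)
  si <- split_index(split_ms, fs, T)
  with_seed(seed, {
    u <- runif(T)
    sample_chain_core(truth$pi, A_pre, A_post, si, u)
  })
}

#' Draw state-conditional Gaussian emissions along a path
#'
#' @param truth a `ground_truth_model`.
#' @param path integer state sequence (values in 1..K).
#' @param seed integer seed or NULL.
#' @return M x length(path) matrix, column t drawn from
#'   `N(mu[path[t], ], Sigma[path[t], , ])`.
#' @export
sample_emissions <- function(truth, path, seed = NULL) {
  if (any(path < 1 | path > truth$K))
    stop("path contains a state index outside 1..K", call. = FALSE)
  M <- truth$M
  with_seed(seed, {
    Z <- matrix(rnorm(M * length(path)), M)
    Y <- matrix(0, M, length(path))
    for (k in sort(unique(path))) {
      idx <- which(path == k)
      L <- chol(truth$Sigma[k, , ])          # upper triangular
      Y[, idx] <- truth$mu[k, ] + crossprod(L, Z[, idx, drop = FALSE])
    }
    Y
  })
}

#' Generate one subject-condition recording
#'
#' Builds the subject's ERP template by drawing state-conditional Gaussian
#' samples along `path`, smoothing each channel with a short moving average,
#' and adding the condition's component-window amplitude shift; then stacks
#' `n_trials` noisy trials around the template. Pre-onset baseline samples
#' carry noise only.
#'
#' @param truth a `ground_truth_model`.
#' @param path post-onset state sequence (defines the template dynamics).
#' @param config a `synth_config`.
#' @param condition condition label.
#' @param seed integer seed or NULL.
#' @return list with `template` (M x T_total, pre-onset part zero) and
#'   `trials` (n_trials x M x T_total array), plus timing metadata.
#' @export
sample_subject_data <- function(truth, path, config, condition, seed = NULL) {
  M <- truth$M
  fs <- config$fs
  n_pre <- round(-config$epoch_start_ms * fs / 1000)
  with_seed(seed, {
    Y <- sample_emissions(truth, path, seed = NULL)
    Y <- t(apply(Y, 1, moving_average, width = config$smooth_len))
    ce <- truth$component_effect
    if (identical(condition, ce$condition)) {
      tt <- sample_times(length(path), fs, 0)
      in_win <- tt >= ce$window_ms[1] & tt < ce$window_ms[2]
      ch <- if (is.character(ce$channels)) match(ce$channels, truth$channels)
            else as.integer(ce$channels)
      if (anyNA(ch)) stop("component_effect channels not in montage", call. = FALSE)
      Y[ch, in_win] <- Y[ch, in_win] + ce$shift
    }
    template <- cbind(matrix(0, M, n_pre), Y)
    T_total <- ncol(template)
    trials <- array(0, c(config$n_trials, M, T_total))
    for (tr in seq_len(config$n_trials))
      trials[tr, , ] <- template +
        if (config$noise_sd > 0)
          matrix(rnorm(M * T_total, sd = config$noise_sd), M) else 0
    list(template = template, trials = trials, fs = fs,
         t0_ms = config$epoch_start_ms, channels = truth$channels)
  })
}

#' Generate a full two-condition synthetic study
#'
#' Simulates `n_subjects` subjects, each measured under both conditions.
#' Per-subject transition matrices are Dirichlet perturbations of the group
#' matrix (concentration `subject_jitter`); state paths, ERP templates and
#' noisy trials are drawn per subject and condition. Fully reproducible
#' given `config$seed`.
#'
#' @param config a `synth_config`.
#' @param truth a `ground_truth_model`.
#' @return list of class `synth_study` with `dataset` (a `trial_dataset`)
#'   and `truth` (the model, all ground-truth paths, per-subject transition
#'   matrices).
#' @export
generate_study <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ground_truth_model"))
  conditions <- names(truth$late_bias)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  T_post <- round(config$epoch_end_ms * config$fs / 1000)
  with_seed(config$seed, {
    epochs <- paths <- stats::setNames(vector("list", length(subjects)), subjects)
    A_subject <- stats::setNames(vector("list", length(subjects)), subjects)
    for (s in subjects) {
      A_s <- truth$A
      for (i in seq_len(truth$K))
        A_s[i, ] <- rdirichlet1(config$subject_jitter * truth$A[i, ])
      A_subject[[s]] <- A_s
      truth_s <- truth
      truth_s$A <- A_s
      epochs[[s]] <- paths[[s]] <- stats::setNames(vector("list", length(conditions)),
                                                   conditions)
      for (cond in conditions) {
        p <- sample_state_sequence(truth_s, cond, T_post, config$fs,
                                   config$split_ms, seed = NULL)
        sd_ <- sample_subject_data(truth_s, p, config, cond, seed = NULL)
        paths[[s]][[cond]] <- p
        epochs[[s]][[cond]] <- epoch_set(sd_$trials, config$fs,
                                         config$epoch_start_ms,
                                         truth$channels, s, cond)
      }
    }
    dataset <- trial_dataset(epochs, subjects, conditions, truth$channels,
                             config$fs, config$epoch_start_ms)
    structure(list(dataset = dataset,
                   truth = list(model = truth, paths = paths,
                                A_subject = A_subject),
                   config = config),
              class = "synth_study")
  })
}
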