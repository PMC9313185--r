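# State temporal metrics: fractional occupancy, mean dwell time, occupancy
# timecourses, early/late period occupancy, and state matching between two
# independently fitted models.

#' Fraction of time per state
#'
#' @param path integer state sequence (values 1..K).
#' @param K number of states.
#' @return length-K proportion vector summing to 1.
#' @export
fraction_of_time <- function(path, K) {
  if (!length(path)) stop("empty path", call. = FALSE)
  tabulate(path, nbins = K) / length(path)
}

#' Mean dwell time per state
#'
#' Run-length encodes the path; per state, the mean length (samples) of its
#' runs. States never visited get `NA`.
#'
#' @inheritParams fraction_of_time
#' @return length-K numeric vector with attribute `n_visits` (runs per
#'   state).
#' @export
mean_dwell_time <- function(path, K) {
  if (!length(path)) stop("empty path", call. = FALSE)
  r <- rle(as.integer(path))
  dwell <- rep(NA_real_, K)
  visits <- integer(K)
  for (k in seq_len(K)) {
    runs <- r$lengths[r$values == k]
    visits[k] <- length(runs)
    if (length(runs)) dwell[k] <- mean(runs)
  }
  structure(dwell, n_visits = visits)
}

#' Group occupancy timecourse
#'
#' State probability at each time point across subjects, either as the mean
#' posterior (`posterior-mean`, from per-subject gamma matrices) or as the
#' proportion of subjects decoded into each state (`viterbi-proportion`,
#' from per-subject paths).
#'
#' @param x list over subjects: T x K gamma matrices (posterior mode) or
#'   integer paths (viterbi mode). All subjects must share T.
#' @param mode "posterior-mean" or "viterbi-proportion".
#' @param K number of states (required in viterbi mode).
#' @return K x T matrix; every column sums to 1.
#' @export
occupancy_timecourse <- function(x, mode = c("posterior-mean",
                                             "viterbi-proportion"), K = NULL) {
  mode <- match.arg(mode)
  if (mode == "posterior-mean") {
    Ts <- vapply(x, nrow, 0L)
    if (length(unique(Ts)) != 1)
      stop("subjects have unequal sequence lengths", call. = FALSE)
    t(Reduce(`+`, x) / length(x))
  } else {
    Ts <- vapply(x, length, 0L)
    if (length(unique(Ts)) != 1)
      stop("subjects have unequal sequence lengths", call. = FALSE)
    if (is.null(K)) K <- max(vapply(x, max, 0L))
    P <- matrix(0, K, Ts[1])
    for (p in x)
      P <- P + vapply(p, function(s) {
        e <- numeric(K); e[s] <- 1; e
      }, numeric(K))
    P / length(x)
  }
}

#' Early/late period occupancy of a path
#'
#' Splits the path at `split_ms`: the early period is samples with time
#' `<= split_ms`, the late period strictly after. Per-period state fractions
#' each sum to 1; the overall fractions are the period-weighted mixture.
#'
#' @inheritParams fraction_of_time
#' @param split_ms boundary (ms).
#' @param fs sampling rate (Hz).
#' @param t_origin_ms time of the first path sample (ms), default 0
#'   (post-onset path).
#' @return list with `fraction_early`, `fraction_late` (length-K vectors),
#'   `w_early`, `w_late` (period sample proportions).
#' @export
period_occupancy <- function(path, split_ms, fs, t_origin_ms = 0, K) {
  tt <- sample_times(length(path), fs, t_origin_ms)
  if (split_ms < tt[1] || split_ms >= tt[length(tt)] + 1000 / fs)
    stop("split time lies outside the path's span", call. = FALSE)
  early <- tt <= split_ms
  late <- if (all(early)) rep(NA_real_, K)  # split at the end of the span
          else fraction_of_time(path[!early], K)
  list(fraction_early = fraction_of_time(path[early], K),
       fraction_late = late,
       w_early = mean(early), w_late = mean(!early))
}

#' Per-subject state metrics table
#'
#' @param paths nested list `paths[[subject]][[condition]]` of decoded state
#'   sequences (all sharing the post-onset time grid).
#' @param K number of states.
#' @param split_ms early/late boundary (ms post-onset).
#' @param fs sampling rate (Hz).
#' @param t_origin_ms time of the first path sample.
#' @return data.frame with one row per subject x condition x state:
#'   `fraction_of_time`, `mean_dwell_time` (samples), `dwell_ms`,
#'   `n_visits`, `fraction_early`, `fraction_late`, `present`.
#' @export
state_metrics <- function(paths, K, split_ms, fs, t_origin_ms = 0) {
  rows <- list()
  for (s in names(paths)) for (cond in names(paths[[s]])) {
    p <- paths[[s]][[cond]]
    f <- fraction_of_time(p, K)
    d <- mean_dwell_time(p, K)
    po <- period_occupancy(p, split_ms, fs, t_origin_ms, K)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, condition = cond, state = seq_len(K),
      fraction_of_time = f, mean_dwell_time = as.numeric(d),
      dwell_ms = as.numeric(d) * 1000 / fs,
      n_visits = attr(d, "n_visits"),
      fraction_early = po$fraction_early, fraction_late = po$fraction_late,
      present = f > 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match states between two fitted models
#'
#' States are compared through the upper triangle of their correlation-form
#' connectivity matrices (Pearson correlation of the off-diagonal
#' patterns); the returned permutation maximises total similarity over all
#' bijections, ties broken toward the lexicographically first assignment.
#' Degenerate (constant) patterns contribute similarity 0 with a warning.
#'
#' @param fit_A,fit_B `hmm_params` (or `hmm_fit`) with equal K and M and a
#'   shared channel order.
#' @return list of class `state_matching`: `perm` (integer vector;
#'   `perm[i]` is the state of B matched to state i of A, so relabelling B's
#'   state `perm[i]` as `i` aligns the two fits), `similarity` (per matched
#'   pair), `similarity_matrix`.
#' @export
match_states <- function(fit_A, fit_B) {
  if (inherits(fit_A, "hmm_fit")) fit_A <- fit_A$params
  if (inherits(fit_B, "hmm_fit")) fit_B <- fit_B$params
  stopifnot(fit_A$K == fit_B$K, fit_A$M == fit_B$M)
  K <- fit_A$K
  vecs_A <- lapply(seq_len(K), function(k) upper_tri_vec(fc_matrix(fit_A, k, "correlation")))
  vecs_B <- lapply(seq_len(K), function(k) upper_tri_vec(fc_matrix(fit_B, k, "correlation")))
  degen <- FALSE
  S <- matrix(0, K, K)
  flat <- function(v) length(v) < 2 || is.na(sd(v)) || sd(v) == 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (flat(vecs_A[[i]]) || flat(vecs_B[[j]])) {
      degen <- TRUE
      S[i, j] <- 0
    } else S[i, j] <- cor(vecs_A[[i]], vecs_B[[j]])
  }
  if (degen)
    warning("constant connectivity pattern(s); similarity set to 0",
            call. = FALSE)
  perms <- all_permutations(K)
  scores <- perms            # reuse dims
  total <- apply(perms, 1, function(p) sum(S[cbind(seq_len(K), p)]))
  best <- perms[which.max(total), ]   # which.max: first (lexicographic) tie wins
  structure(list(perm = as.integer(best),
                 similarity = S[cbind(seq_len(K), best)],
                 similarity_matrix = S),
            class = "state_matching")
}

#' Relabel a fitted model's states
#'
#' Applies a state permutation (e.g. from [match_states()]) so that state
#' `perm[i]` of the input becomes state `i` of the output; decoded paths and
#' posteriors are relabelled consistently.
#'
#' @param fit an `hmm_fit`.
#' @param perm integer permutation as returned by [match_states()].
#' @return the relabelled `hmm_fit`.
#' @export
relabel_states <- function(fit, perm) {
  stopifnot(inherits(fit, "hmm_fit"), setequal(perm, seq_len(fit$params$K)))
  inv <- order(perm)    # inv[old_label] = new_label
  p <- fit$params
  p$pi <- p$pi[perm]
  p$A <- p$A[perm, perm, drop = FALSE]
  p$mu <- p$mu[perm, , drop = FALSE]
  p$Sigma <- p$Sigma[perm, , , drop = FALSE]
  fit$params <- p
  fit$paths <- lapply(fit$paths, function(s) inv[s])
  fit$posteriors$gamma <- lapply(fit$posteriors$gamma,
                                 function(g) g[, perm, drop = FALSE])
  fit$posteriors$xi_sum <- fit$posteriors$xi_sum[perm, perm, drop = FALSE]
  fit
}
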