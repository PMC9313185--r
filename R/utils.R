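# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample times in ms: sample i (1-based) sits at t0_ms + (i-1) * 1000/fs.
sample_times <- function(n, fs, t0_ms = 0) t0_ms + (seq_len(n) - 1L) * 1000 / fs

# Moving average with edge-shrinking windows (no NA padding).
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Row-stochastic normalisation.
normalize_rows <- function(A) {
  s <- rowSums(A)
  if (any(s <= 0)) stop("cannot normalise a row with non-positive sum", call. = FALSE)
  A / s
}

# One Dirichlet draw with concentration vector `alpha`.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# All permutations of 1..n in lexicographic order (rows). n! rows; n small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

upper_tri_vec <- function(S) S[upper.tri(S)]

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}
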