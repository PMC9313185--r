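# Group inference: paired t-tests, the all-within 2x2x2 repeated-measures
# ANOVA via per-subject contrasts, simple effects, and subject exclusion.
#
# With two levels per within-subject factor every effect has 1 numerator
# df, and its exact test is the one-sample t on the per-subject contrast
# (F = t^2); sphericity is moot.

# Core paired-t on a difference vector; returns t, df, p, flag.
paired_t_core <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0, n = n,
                            flag = "degenerate-zero"))
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, mean_diff = m, n = n,
                flag = "degenerate-infinite"))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1), mean_diff = m, n = n,
       flag = "none")
}

#' Paired t-test
#'
#' Two-sided paired t-test on subject-matched values: `t = mean(d) /
#' (sd(d)/sqrt(n))` with `d = x - y` and the sample standard deviation.
#' Zero-variance differences are flagged (`degenerate-zero` when the mean is
#' also 0, giving t = 0 and p = 1; `degenerate-infinite` otherwise).
#'
#' @param x,y per-subject values, paired by position, length >= 3.
#' @return list of class `ttest_result`: `t`, `df` (= n - 1), `p`,
#'   `mean_diff`, `n`, `flag`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  structure(paired_t_core(x - y), class = "ttest_result")
}

#' Exclude subjects lacking required states
#'
#' Drops every subject for whom any required state is absent (never
#' visited) in any condition x period cell entering the repeated-measures
#' analysis, mirroring the exclusion of subjects that do not exhibit a
#' state.
#'
#' @param metrics a [state_metrics()] table covering both conditions.
#' @param required_states integer state indices that must be present.
#' @return list with `metrics` (filtered table), `kept` and `excluded`
#'   (data.frame subject/reason).
#' @export
exclude_incomplete <- function(metrics, required_states) {
  subjects <- unique(metrics$subject)
  if (!length(required_states))
    return(list(metrics = metrics, kept = subjects,
                excluded = data.frame(subject = character(0),
                                      reason = character(0))))
  bad <- list()
  for (s in subjects) {
    rows <- metrics[metrics$subject == s & metrics$state %in% required_states, ]
    miss <- rows[!rows$present | rows$fraction_early == 0 |
                   rows$fraction_late == 0, ]
    if (nrow(miss))
      bad[[s]] <- paste0("state ", miss$state[1], " absent in ",
                         miss$condition[1], " (",
                         if (!miss$present[1]) "whole epoch"
                         else if (miss$fraction_early[1] == 0) "early period"
                         else "late period", ")")
  }
  kept <- setdiff(subjects, names(bad))
  if (length(kept) < 3)
    stop("fewer than 3 subjects remain after exclusion", call. = FALSE)
  list(metrics = metrics[metrics$subject %in% kept, ],
       kept = kept,
       excluded = data.frame(subject = names(bad),
                             reason = unlist(bad, use.names = FALSE)))
}

# Validate and return the cell array n x 2 x 2 x 2 with dimnames
# (subject, condition, state, period).
check_cells <- function(cells) {
  if (length(dim(cells)) != 4 || !all(dim(cells)[2:4] == 2))
    stop("cells must be an n x 2 x 2 x 2 array", call. = FALSE)
  if (anyNA(cells)) {
    idx <- which(is.na(cells), arr.ind = TRUE)[1, ]
    dn <- dimnames(cells)
    stop("missing cell for subject ", dn[[1]][idx[1]], " (",
         dn[[2]][idx[2]], ", ", dn[[3]][idx[3]], ", ", dn[[4]][idx[4]], ")",
         call. = FALSE)
  }
  cells
}

anova_factors <- c("condition", "state", "period")

#' Three-way all-within repeated-measures ANOVA (2 x 2 x 2)
#'
#' Tests the three main effects, three two-way interactions and the
#' three-way interaction of a fully within-subject 2 x 2 x 2 design. Each
#' effect is evaluated exactly as the one-sample t on its per-subject
#' contrast (difference of cell means with signs given by the effect's
#' factor codings); reported as `F = t^2` with df (1, n - 1).
#'
#' @param cells n x 2 x 2 x 2 numeric array, dimensions subject, condition,
#'   state, period (in that order), with complete cells.
#' @return list of class `anova_result`: `table` (effect, F, df1, df2, p,
#'   flag), `n_subjects`.
#' @export
rm_anova_222 <- function(cells) {
  cells <- check_cells(cells)
  n <- dim(cells)[1]
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  codes <- list(c(1, -1), c(1, -1), c(1, -1))
  effects <- list(condition = 1L, state = 2L, period = 3L,
                  `condition:state` = c(1L, 2L),
                  `condition:period` = c(1L, 3L),
                  `state:period` = c(2L, 3L),
                  `condition:state:period` = c(1L, 2L, 3L))
  rows <- lapply(names(effects), function(ef) {
    inv <- effects[[ef]]
    # contrast weight of cell (i,j,k) = product of the +/-1 codings of the
    # factors in the effect; uninvolved factors contribute weight 1
    wf <- lapply(1:3, function(f) if (f %in% inv) codes[[f]] else c(1, 1))
    W <- array(outer(outer(wf[[1]], wf[[2]]), wf[[3]]), c(2, 2, 2))
    W <- W / 2^(3 - length(inv)) / 2^length(inv)  # difference-of-means scale
    scores <- apply(cells, 1, function(x) sum(array(x, c(2, 2, 2)) * W))
    tt <- paired_t_core(scores)
    data.frame(effect = ef, F = tt$t^2, df1 = 1L, df2 = n - 1L,
               p = if (tt$flag == "degenerate-zero") 1 else
                 pf(tt$t^2, 1, n - 1, lower.tail = FALSE),
               flag = tt$flag)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n_subjects = n), class = "anova_result")
}

#' Simple effects in the 2 x 2 x 2 design
#'
#' Paired t (reported as F = t^2, df 1 and n - 1) between the two levels of
#' `factor`, holding the other two factors fixed. With `within = NULL` all
#' four slices of the other factors are reported.
#'
#' @inheritParams rm_anova_222
#' @param factor one of "condition", "state", "period".
#' @param within named list fixing levels of the other factors (level names
#'   as in `dimnames(cells)`); NULL = all combinations.
#' @return data.frame with the fixed levels, `F`, `df1`, `df2`, `p`,
#'   `mean_diff` (level1 - level2) and `flag`.
#' @export
simple_effects <- function(cells, factor = anova_factors, within = NULL) {
  cells <- check_cells(cells)
  factor <- match.arg(factor)
  dn <- dimnames(cells)[2:4]
  names(dn) <- anova_factors
  others <- setdiff(anova_factors, factor)
  grids <- if (is.null(within)) {
    expand.grid(a = dn[[others[1]]], b = dn[[others[2]]],
                stringsAsFactors = FALSE)
  } else {
    data.frame(a = within[[others[1]]], b = within[[others[2]]])
  }
  pick <- function(lev_factor, lev_a, lev_b) {
    idx <- stats::setNames(vector("list", 3), anova_factors)
    idx[[factor]] <- lev_factor
    idx[[others[1]]] <- lev_a
    idx[[others[2]]] <- lev_b
    cells[, idx$condition, idx$state, idx$period]
  }
  rows <- lapply(seq_len(nrow(grids)), function(i) {
    x <- pick(dn[[factor]][1], grids$a[i], grids$b[i])
    y <- pick(dn[[factor]][2], grids$a[i], grids$b[i])
    tt <- paired_t_core(x - y)
    out <- data.frame(factor = factor, grids$a[i], grids$b[i],
                      F = tt$t^2, df1 = 1L, df2 = tt$df,
                      p = if (tt$flag == "degenerate-zero") 1 else
                        pf(tt$t^2, 1, tt$df, lower.tail = FALSE),
                      mean_diff = tt$mean_diff, flag = tt$flag)
    names(out)[2:3] <- others
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
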