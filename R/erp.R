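# ERP conditioning: epoch containers, average reference, baseline
# correction, trial averaging, component-window amplitudes and paired-t
# electrode selection.

#' Epoched single-subject recording
#'
#' @param trials n_trials x M x T numeric array (trials x channels x time).
#' @param fs sampling rate (Hz).
#' @param t0_ms time of the first sample relative to stimulus onset (ms).
#' @param channels unique channel labels, length M.
#' @param subject,condition identifiers.
#' @return list of class `epoch_set`.
#' @export
epoch_set <- function(trials, fs, t0_ms, channels, subject = NA_character_,
                      condition = NA_character_) {
  if (length(dim(trials)) != 3)
    stop("trials must be a 3-d array (trials x channels x time)", call. = FALSE)
  if (dim(trials)[1] < 1) stop("empty trial stack", call. = FALSE)
  if (dim(trials)[2] != length(channels))
    stop("channel labels do not match trial array", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  T <- dim(trials)[3]
  if (max(sample_times(T, fs, t0_ms)) < 0)
    stop("epoch does not extend past stimulus onset", call. = FALSE)
  structure(list(trials = trials, fs = fs, t0_ms = t0_ms,
                 channels = channels, subject = subject, condition = condition),
            class = "epoch_set")
}

#' Multi-subject, multi-condition trial dataset
#'
#' @param epochs nested list: `epochs[[subject]][[condition]]` is an
#'   `epoch_set`.
#' @param subjects,conditions identifiers in analysis order.
#' @param channels,fs,t0_ms shared acquisition metadata.
#' @return list of class `trial_dataset`.
#' @export
trial_dataset <- function(epochs, subjects, conditions, channels, fs, t0_ms) {
  structure(list(epochs = epochs, subjects = subjects,
                 conditions = conditions, channels = channels, fs = fs,
                 t0_ms = t0_ms),
            class = "trial_dataset")
}

#' Rereference epochs to the channel average
#'
#' Subtracts, at every trial and time sample, the instantaneous mean across
#' channels, so the referenced data have zero channel mean at each sample.
#'
#' @param epochs an `epoch_set` with at least 2 channels.
#' @return the rereferenced `epoch_set`.
#' @export
rereference_average <- function(epochs) {
  d <- dim(epochs$trials)
  if (d[2] < 2)
    stop("average rereferencing needs at least 2 channels", call. = FALSE)
  m <- colMeans(aperm(epochs$trials, c(2, 1, 3)))     # trials x time
  epochs$trials <- epochs$trials - aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts from each trial and channel its mean over the pre-stimulus
#' baseline window `[baseline_start_ms, baseline_end_ms)`.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_start_ms,baseline_end_ms baseline bounds (ms relative to
#'   onset); must lie within `[t0_ms, 0]`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_start_ms = -200,
                             baseline_end_ms = 0) {
  d <- dim(epochs$trials)
  tt <- sample_times(d[3], epochs$fs, epochs$t0_ms)
  if (baseline_start_ms < epochs$t0_ms || baseline_end_ms > 0 ||
      baseline_start_ms >= baseline_end_ms)
    stop("baseline window must lie within [t0_ms, 0]", call. = FALSE)
  idx <- which(tt >= baseline_start_ms & tt < baseline_end_ms)
  if (!length(idx)) stop("baseline window contains no samples", call. = FALSE)
  b <- rowMeans(epochs$trials[, , idx, drop = FALSE], dims = 2)  # trials x channels
  epochs$trials <- epochs$trials - array(b, d)
  epochs
}

#' Average trials into an ERP
#'
#' @param epochs an `epoch_set`.
#' @return list of class `erp_set` with `erp` (M x T), timing metadata and
#'   identifiers carried over.
#' @export
average_trials <- function(epochs) {
  if (dim(epochs$trials)[1] < 1) stop("empty trial stack", call. = FALSE)
  erp <- colMeans(epochs$trials)                      # M x T
  structure(list(erp = erp, fs = epochs$fs, t0_ms = epochs$t0_ms,
                 channels = epochs$channels, subject = epochs$subject,
                 condition = epochs$condition),
            class = "erp_set")
}

#' Default ERP component windows
#'
#' The four post-stimulus latency windows of the classic visual components
#' P1 (90-130 ms), early N1 (100-140 ms), late N1 (180-220 ms) and P3
#' (280-320 ms).
#'
#' @return data.frame with columns `name`, `start_ms`, `end_ms`.
#' @export
component_windows <- function() {
  data.frame(name = c("P1", "earlyN1", "lateN1", "P3"),
             start_ms = c(90, 100, 180, 280),
             end_ms = c(130, 140, 220, 320))
}

#' Mean ERP amplitude per channel and component window
#'
#' Window sample inclusion is half-open: samples with
#' `start_ms <= t < end_ms` in post-onset time.
#'
#' @param erp an `erp_set`.
#' @param windows data.frame as [component_windows()].
#' @return data.frame (channel x window) with columns `channel`, `window`,
#'   `amplitude`.
#' @export
component_amplitudes <- function(erp, windows = component_windows()) {
  tt <- sample_times(ncol(erp$erp), erp$fs, erp$t0_ms)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- which(tt >= windows$start_ms[i] & tt < windows$end_ms[i])
    if (!length(idx))
      stop("window ", windows$name[i], " contains no samples", call. = FALSE)
    data.frame(channel = erp$channels, window = windows$name[i],
               amplitude = rowMeans(erp$erp[, idx, drop = FALSE]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Stack per-subject amplitude tables into one long table.
stack_amplitudes <- function(amps_by_subject) {
  do.call(rbind, lapply(names(amps_by_subject), function(s)
    cbind(subject = s, amps_by_subject[[s]])))
}

#' Select electrodes by paired t-tests on component amplitudes
#'
#' For every channel x window cell a two-sided paired t-test across subjects
#' compares the two conditions' mean amplitudes; a channel is selected if
#' any of its windows is significant at `alpha`. No multiple-comparison
#' correction is applied. Cells whose paired differences are all zero are
#' flagged degenerate and never selected.
#'
#' @param amps_A,amps_B long data.frames with columns `subject`, `channel`,
#'   `window`, `amplitude`, covering identical subject x channel x window
#'   grids (condition A and B).
#' @param alpha per-cell significance level.
#' @param channels channel order for the output; defaults to order of first
#'   appearance in `amps_A`.
#' @return list of class `selection_result`: `selected` (ordered labels),
#'   `per_window` (channel x window table of t, p, selected, degenerate),
#'   `alpha`, `n_subjects`.
#' @export
select_electrodes <- function(amps_A, amps_B, alpha = 0.05,
                              channels = unique(amps_A$channel)) {
  key <- function(d) paste(d$subject, d$channel, d$window, sep = "\r")
  if (!setequal(key(amps_A), key(amps_B)) || nrow(amps_A) != nrow(amps_B))
    stop("amplitude tables cover different subject/channel/window grids",
         call. = FALSE)
  subjects <- unique(amps_A$subject)
  if (length(subjects) < 3)
    stop("paired selection needs at least 3 subjects", call. = FALSE)
  amps_B <- amps_B[match(key(amps_A), key(amps_B)), ]
  windows <- unique(amps_A$window)
  grid <- expand.grid(channel = channels, window = windows,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- amps_A$channel == grid$channel[i] & amps_A$window == grid$window[i]
    d <- amps_A$amplitude[sel] - amps_B$amplitude[sel]
    tt <- paired_t_core(d)
    data.frame(channel = grid$channel[i], window = grid$window[i],
               t = tt$t, p = tt$p,
               degenerate = tt$flag == "degenerate-zero")
  })
  per_window <- do.call(rbind, res)
  per_window$selected <- per_window$p < alpha & !per_window$degenerate
  if (any(per_window$degenerate))
    warning("zero-variance paired differences in ",
            sum(per_window$degenerate), " channel x window cell(s); ",
            "flagged degenerate and not selected", call. = FALSE)
  selected <- channels[channels %in% per_window$channel[per_window$selected]]
  structure(list(selected = selected, per_window = per_window,
                 alpha = alpha, n_subjects = length(subjects)),
            class = "selection_result")
}

#' Tally selected electrodes by scalp region
#'
#' @param selection a `selection_result`.
#' @param region_map named character vector mapping channel labels to region
#'   labels.
#' @return named integer vector of counts, one entry per region of the map
#'   (zero counts included); sums to the number of selected channels.
#' @export
region_tally <- function(selection, region_map) {
  sel <- selection$selected
  if (!all(sel %in% names(region_map)))
    stop("selected channel(s) missing from region map: ",
         paste(setdiff(sel, names(region_map)), collapse = ", "), call. = FALSE)
  regions <- unique(unname(region_map))
  counts <- vapply(regions, function(r)
    sum(region_map[sel] == r), integer(1))
  stats::setNames(counts, regions)
}
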