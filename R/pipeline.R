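# End-to-end orchestration: preprocess -> ERP -> electrode selection ->
# per-condition HMM fits -> state matching -> temporal metrics -> group
# statistics -> report bundle.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Defaults follow the reference analysis: K = 4 states, 20 EM restarts,
#' selection alpha 0.05 (uncorrected), component windows P1/early N1/late
#' N1/P3, epoch -200..3000 ms, early/late split at 1100 ms, HMM run on
#' post-onset samples of the selected channels, channels z-scored within
#' subject.
#'
#' @param seed master seed; every random draw of the run derives from it.
#' @param preprocessing list: `rereference` flag, `baseline` window (ms).
#' @param selection list: `alpha`, `windows` data.frame.
#' @param hmm list: `K`, `n_restarts`, `tol`, `max_iter`,
#'   `post_onset_only`, `standardize`.
#' @param metrics list: `split_ms`, `timecourse_mode`.
#' @param stats list: `required_states` ("dominant" = the two states with
#'   the highest overall fractional occupancy, or explicit indices).
#' @param synth optional [synth_config()] used when no dataset is given.
#' @param synth_M channel count of the simulated montage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            preprocessing = list(),
                            selection = list(),
                            hmm = list(),
                            metrics = list(),
                            stats = list(),
                            synth = NULL, synth_M = 8) {
  cfg <- list(
    seed = as.integer(seed),
    preprocessing = utils::modifyList(
      list(rereference = TRUE, baseline = c(-200, 0)), preprocessing),
    selection = utils::modifyList(
      list(alpha = 0.05, windows = component_windows()), selection),
    hmm = utils::modifyList(
      list(K = 4L, n_restarts = 20L, tol = 1e-6, max_iter = 500L,
           post_onset_only = TRUE, standardize = TRUE), hmm),
    metrics = utils::modifyList(
      list(split_ms = 1100, timecourse_mode = "posterior-mean"), metrics),
    stats = utils::modifyList(
      list(required_states = "dominant"), stats),
    synth = synth, synth_M = as.integer(synth_M))
  structure(cfg, class = "pipeline_config")
}

# ERP per subject x condition after optional rereference and baseline.
preprocess_erps <- function(dataset, cfg) {
  erps <- list()
  for (s in dataset$subjects) {
    erps[[s]] <- list()
    for (cond in dataset$conditions) {
      ep <- dataset$epochs[[s]][[cond]]
      if (cfg$preprocessing$rereference) ep <- rereference_average(ep)
      bl <- cfg$preprocessing$baseline
      bl[1] <- max(bl[1], dataset$t0_ms)
      ep <- baseline_correct(ep, bl[1], bl[2])
      erps[[s]][[cond]] <- average_trials(ep)
    }
  }
  erps
}

# Observation sequences for one condition: selected channels, optionally
# post-onset only and z-scored.
build_obs <- function(erps, condition, channels_sel, cfg) {
  lapply(erps, function(by_cond) {
    e <- by_cond[[condition]]
    Y <- e$erp[match(channels_sel, e$channels), , drop = FALSE]
    if (cfg$hmm$post_onset_only) {
      tt <- sample_times(ncol(Y), e$fs, e$t0_ms)
      Y <- Y[, tt >= 0, drop = FALSE]
    }
    if (cfg$hmm$standardize) Y <- standardize_channels(Y)
    Y
  })
}

#' Run the full two-condition analysis pipeline
#'
#' Stages: preprocessing (average reference, baseline) -> trial averaging ->
#' component-window amplitudes -> paired-t electrode selection -> HMM fit
#' per condition on the selected channels (identical restart seeds for both
#' conditions) -> state matching (second condition relabelled onto the
#' first) -> Viterbi paths -> per-subject state metrics and occupancy
#' timecourses -> subject exclusion -> paired t-tests, 2x2x2
#' repeated-measures ANOVA on early/late fractional occupancy of the two
#' dominant states, and simple effects.
#'
#' @param config a [pipeline_config()].
#' @param dataset a `trial_dataset`, or NULL to simulate one from
#'   `config$synth`.
#' @param truth optional `ground_truth_model` for simulation.
#' @return list of class `report_bundle`.
#' @export
run_pipeline <- function(config, dataset = NULL, truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  study_truth <- NULL

  if (is.null(dataset)) {
    if (is.null(config$synth))
      stop("no dataset given and no synth block in the config", call. = FALSE)
    if (is.null(truth))
      truth <- build_ground_truth(K = config$hmm$K, M = config$synth_M,
                                  seed = config$seed)
    study <- generate_study(config$synth, truth)
    dataset <- study$dataset
    study_truth <- study$truth
    note("simulated study: ", config$synth$n_subjects, " subjects, ",
         truth$M, " channels, fs ", config$synth$fs, " Hz, seed ",
         config$synth$seed)
  }
  conditions <- dataset$conditions
  if (length(conditions) != 2)
    stop("the pipeline compares exactly 2 conditions", call. = FALSE)
  cond_A <- conditions[1]
  cond_B <- conditions[2]

  erps <- preprocess_erps(dataset, config)
  note("preprocessed ", length(erps), " subjects (rereference = ",
       config$preprocessing$rereference, ")")

  amps <- lapply(conditions, function(cond)
    stack_amplitudes(lapply(erps, function(e)
      component_amplitudes(e[[cond]], config$selection$windows))))
  names(amps) <- conditions
  selection <- select_electrodes(amps[[cond_A]], amps[[cond_B]],
                                 alpha = config$selection$alpha,
                                 channels = dataset$channels)
  if (!length(selection$selected))
    stop("no electrodes selected at alpha = ", config$selection$alpha,
         "; lower alpha or increase the effect size", call. = FALSE)
  note("selected ", length(selection$selected), " of ",
       length(dataset$channels), " channels: ",
       paste(selection$selected, collapse = ", "))
  tally <- if (!is.null(study_truth))
    region_tally(selection, study_truth$model$regions) else NULL

  K <- config$hmm$K
  fit_seed <- config$seed + 1000L   # same restart seed sequence per condition
  fits <- lapply(conditions, function(cond)
    fit_hmm(build_obs(erps, cond, selection$selected, config),
            K = K, n_restarts = config$hmm$n_restarts, tol = config$hmm$tol,
            max_iter = config$hmm$max_iter, seed = fit_seed))
  names(fits) <- conditions
  note("fitted HMMs: loglik ", cond_A, " = ",
       round(fits[[cond_A]]$posteriors$loglik, 2), ", ", cond_B, " = ",
       round(fits[[cond_B]]$posteriors$loglik, 2))

  matching <- match_states(fits[[cond_A]], fits[[cond_B]])
  fits[[cond_B]] <- relabel_states(fits[[cond_B]], matching$perm)
  note("state matching (", cond_B, " -> ", cond_A, "): ",
       paste(matching$perm, collapse = " "), "; similarity ",
       paste(round(matching$similarity, 3), collapse = " "))

  fs <- dataset$fs
  t_origin <- if (config$hmm$post_onset_only) 0 else dataset$t0_ms
  paths <- stats::setNames(lapply(dataset$subjects, function(s)
    stats::setNames(lapply(conditions, function(cond)
      fits[[cond]]$paths[[s]]), conditions)), dataset$subjects)
  metrics <- state_metrics(paths, K, config$metrics$split_ms, fs, t_origin)

  timecourse <- lapply(conditions, function(cond)
    if (config$metrics$timecourse_mode == "posterior-mean")
      occupancy_timecourse(fits[[cond]]$posteriors$gamma, "posterior-mean")
    else
      occupancy_timecourse(fits[[cond]]$paths, "viterbi-proportion", K = K))
  names(timecourse) <- conditions

  # dominant states = two highest overall fractional occupancies
  avg_frac <- vapply(seq_len(K), function(k)
    mean(metrics$fraction_of_time[metrics$state == k]), 0)
  dominant <- sort(order(avg_frac, decreasing = TRUE)[1:2])
  # of the two, the weak-connectivity one has the lower mean |off-diagonal|
  # correlation in the first condition's fit
  offd <- vapply(dominant, function(k)
    mean(abs(upper_tri_vec(fc_matrix(fits[[cond_A]], k, "correlation")))), 0)
  weak_state <- if (all(is.finite(offd))) dominant[which.min(offd)]
                else dominant[2]   # single-channel fit: no connectivity notion
  if (!all(is.finite(offd)))
    note("connectivity undefined (single channel); weak state defaulted to ",
         weak_state)
  strong_state <- setdiff(dominant, weak_state)
  note("dominant states: ", paste(dominant, collapse = ", "),
       "; weak-connectivity state: ", weak_state)

  req <- config$stats$required_states
  required <- if (identical(req, "dominant")) dominant else as.integer(req)
  excl <- exclude_incomplete(metrics, required)
  if (nrow(excl$excluded))
    note("excluded ", nrow(excl$excluded), " subject(s): ",
         paste(excl$excluded$subject, collapse = ", "))

  # paired t-tests on overall fraction of time (all subjects) per state
  ttests <- do.call(rbind, lapply(seq_len(K), function(k) {
    x <- metrics[metrics$state == k & metrics$condition == cond_A, ]
    y <- metrics[metrics$state == k & metrics$condition == cond_B, ]
    y <- y[match(x$subject, y$subject), ]
    tt <- paired_t(x$fraction_of_time, y$fraction_of_time)
    data.frame(measure = "fraction_of_time", state = k, t = tt$t, df = tt$df,
               p = tt$p, mean_diff = tt$mean_diff, n = tt$n, flag = tt$flag)
  }))
  dwell_tests <- do.call(rbind, lapply(seq_len(K), function(k) {
    x <- metrics[metrics$state == k & metrics$condition == cond_A, ]
    y <- metrics[metrics$state == k & metrics$condition == cond_B, ]
    y <- y[match(x$subject, y$subject), ]
    ok <- !is.na(x$mean_dwell_time) & !is.na(y$mean_dwell_time)
    if (sum(ok) < 3) return(NULL)
    tt <- paired_t(x$mean_dwell_time[ok], y$mean_dwell_time[ok])
    data.frame(measure = "mean_dwell_time", state = k, t = tt$t, df = tt$df,
               p = tt$p, mean_diff = tt$mean_diff, n = tt$n, flag = tt$flag)
  }))

  # 2x2x2 cells: early/late fractional occupancy of the two dominant states
  kept <- excl$kept
  state_levels <- c(strong_state, weak_state)
  cells <- array(NA_real_,
                 c(length(kept), 2, 2, 2),
                 dimnames = list(kept, conditions,
                                 paste0("state", state_levels),
                                 c("early", "late")))
  mk <- excl$metrics
  for (i in seq_along(kept)) for (ci in 1:2) for (si in 1:2) {
    row <- mk[mk$subject == kept[i] & mk$condition == conditions[ci] &
                mk$state == state_levels[si], ]
    cells[i, ci, si, 1] <- row$fraction_early
    cells[i, ci, si, 2] <- row$fraction_late
  }
  anova <- rm_anova_222(cells)
  pad_slice <- function(d) {
    for (f in anova_factors) if (is.null(d[[f]])) d[[f]] <- "(both)"
    d[, c("factor", anova_factors, "F", "df1", "df2", "p", "mean_diff", "flag")]
  }
  simple <- rbind(
    pad_slice(simple_effects(cells, "period")),
    pad_slice(simple_effects(cells, "state",
                             within = list(condition = conditions,
                                           period = "early"))),
    pad_slice(simple_effects(cells, "condition",
                             within = list(state = paste0("state", weak_state),
                                           period = c("early", "late")))))

  structure(list(selection = selection, region_tally = tally,
                 fits = fits, matching = matching, metrics = metrics,
                 timecourse = timecourse,
                 stats = list(ttests = rbind(ttests, dwell_tests),
                              anova = anova, simple = simple),
                 dominant_states = dominant, weak_state = weak_state,
                 strong_state = strong_state,
                 excluded = excl$excluded, kept = kept, cells = cells,
                 truth = study_truth, config = config, log = log_lines),
            class = "report_bundle")
}

params_to_list <- function(p)
  list(K = p$K, M = p$M, pi = p$pi, A = p$A, mu = p$mu,
       Sigma = lapply(seq_len(p$K), function(k) p$Sigma[k, , ]))

#' Write a report bundle to disk
#'
#' Emits `selection.csv`, one `fit_<condition>.json` per condition,
#' `matching.json`, `metrics.csv`, `timecourse.tsv`, `stats.csv` and
#' `run_log.txt`.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(name) {
    p <- file.path(out_dir, name)
    paths <<- c(paths, p)
    p
  }

  sel <- bundle$selection$per_window
  if (!is.null(bundle$region_tally)) {
    regions <- bundle$truth$model$regions
    sel$region <- unname(regions[as.character(sel$channel)])
  }
  utils::write.csv(sel, wr("selection.csv"), row.names = FALSE)

  for (cond in names(bundle$fits)) {
    f <- bundle$fits[[cond]]
    jsonlite::write_json(
      c(params_to_list(f$params),
        list(loglik = f$posteriors$loglik, loglik_trace = f$loglik_trace,
             restart_index = f$restart_index, seed = f$seed_used)),
      wr(paste0("fit_", cond, ".json")), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(perm = bundle$matching$perm,
                            similarity = bundle$matching$similarity,
                            similarity_matrix = bundle$matching$similarity_matrix),
                       wr("matching.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$metrics, wr("metrics.csv"), row.names = FALSE)

  tc <- do.call(rbind, lapply(names(bundle$timecourse), function(cond) {
    P <- bundle$timecourse[[cond]]
    data.frame(condition = cond,
               state = rep(seq_len(nrow(P)), ncol(P)),
               time_index = rep(seq_len(ncol(P)), each = nrow(P)),
               probability = as.vector(P))
  }))
  write.table(tc, wr("timecourse.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  st <- bundle$stats
  stats_rows <- rbind(
    data.frame(analysis = "ttest", effect = paste0(st$ttests$measure,
                                                   "_state", st$ttests$state),
               statistic = st$ttests$t, df1 = NA, df2 = st$ttests$df,
               p = st$ttests$p, n = st$ttests$n, flag = st$ttests$flag),
    data.frame(analysis = "anova", effect = st$anova$table$effect,
               statistic = st$anova$table$F, df1 = st$anova$table$df1,
               df2 = st$anova$table$df2, p = st$anova$table$p,
               n = st$anova$n_subjects, flag = st$anova$table$flag),
    data.frame(analysis = paste0("simple_", st$simple$factor),
               effect = apply(st$simple, 1, function(r)
                 paste0(r["factor"], "@",
                        paste(r[setdiff(c("condition", "state", "period"),
                                        r["factor"])], collapse = ","))),
               statistic = st$simple$F, df1 = st$simple$df1,
               df2 = st$simple$df2, p = st$simple$p,
               n = st$simple$df2 + 1, flag = st$simple$flag))
  utils::write.csv(stats_rows, wr("stats.csv"), row.names = FALSE)

  writeLines(c(paste0("erpstates run, seed ", bundle$config$seed),
               paste0("R ", R.version.string),
               bundle$log), wr("run_log.txt"))
  invisible(paths)
}
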