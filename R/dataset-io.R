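# Plain-text dataset interchange: a JSON manifest plus one TSV per trial
# (rows = time samples, columns = channels). Deliberately dependency-light
# and diff-able; adapters for binary EEG formats are an extension point.

trial_filename <- function(subject, condition, trial)
  sprintf("sub-%s_cond-%s_trial-%03d.tsv", subject, condition, trial)

#' Write a trial dataset to a directory
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  listing <- list()
  for (s in dataset$subjects) for (cond in dataset$conditions) {
    ep <- dataset$epochs[[s]][[cond]]
    n <- dim(ep$trials)[1]
    files <- vapply(seq_len(n), function(tr) trial_filename(s, cond, tr), "")
    for (tr in seq_len(n)) {
      m <- t(ep$trials[tr, , ])                     # time x channels
      colnames(m) <- dataset$channels
      write.table(m, file.path(dir, files[tr]), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    listing[[length(listing) + 1L]] <- list(subject = s, condition = cond,
                                            n_trials = n, files = files)
  }
  manifest <- list(fs = dataset$fs, t0_ms = dataset$t0_ms,
                   channels = dataset$channels, subjects = dataset$subjects,
                   conditions = dataset$conditions, trials = listing)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial dataset from a directory
#'
#' Expects the layout written by [write_dataset()]: `manifest.json` plus one
#' TSV per trial with channel labels as the header. Shape or label
#' mismatches are reported with the offending file name.
#'
#' @param dir dataset directory.
#' @return a `trial_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  channels <- manifest$channels
  epochs <- stats::setNames(vector("list", length(manifest$subjects)),
                            manifest$subjects)
  trials_tab <- manifest$trials
  for (i in seq_len(nrow(trials_tab))) {
    s <- trials_tab$subject[i]
    cond <- trials_tab$condition[i]
    files <- trials_tab$files[[i]]
    stack <- NULL
    for (j in seq_along(files)) {
      f <- file.path(dir, files[j])
      if (!file.exists(f)) stop("trial file listed in manifest is missing: ",
                                files[j], call. = FALSE)
      m <- tryCatch(read.table(f, header = TRUE, sep = "\t",
                               check.names = FALSE, colClasses = "numeric"),
                    error = function(e)
                      stop("cannot parse ", files[j], ": ",
                           conditionMessage(e), call. = FALSE))
      if (!identical(colnames(m), channels))
        stop("channel header of ", files[j],
             " does not match the manifest", call. = FALSE)
      if (is.null(stack))
        stack <- array(0, c(length(files), length(channels), nrow(m)))
      else if (nrow(m) != dim(stack)[3])
        stop("trial length of ", files[j],
             " differs from earlier trials", call. = FALSE)
      stack[j, , ] <- t(as.matrix(m))
    }
    if (is.null(epochs[[s]])) epochs[[s]] <- list()
    epochs[[s]][[cond]] <- epoch_set(stack, manifest$fs, manifest$t0_ms,
                                     channels, s, cond)
  }
  trial_dataset(epochs, manifest$subjects, manifest$conditions, channels,
                manifest$fs, manifest$t0_ms)
}
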