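make_epochs <- function(trials, fs = 1000, t0_ms = -200,
                        channels = paste0("ch", seq_len(dim(trials)[2])))
  epoch_set(trials, fs, t0_ms, channels, "S01", "comfort")

test_that("average rereferencing zeroes the channel mean at every sample", {
  set.seed(1)
  ep <- make_epochs(array(rnorm(5 * 4 * 300), c(5, 4, 300)))
  rr <- rereference_average(ep)
  m <- apply(rr$trials, c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-12)
  # idempotence
  rr2 <- rereference_average(rr)
  expect_equal(rr2$trials, rr$trials, tolerance = 1e-12)
  # hand case: (3, 1) -> (1, -1)
  ep2 <- make_epochs(array(c(3, 1), c(1, 2, 1)), t0_ms = 0)
  expect_equal(as.vector(rereference_average(ep2)$trials), c(1, -1))
  expect_error(rereference_average(make_epochs(array(1:5, c(1, 1, 5)), t0_ms = 0)),
               "at least 2 channels")
})

test_that("baseline correction removes the pre-stimulus mean", {
  set.seed(2)
  ep <- make_epochs(array(rnorm(4 * 3 * 500), c(4, 3, 500)))
  bc <- baseline_correct(ep, -200, 0)
  tt <- erpstates:::sample_times(500, 1000, -200)
  idx <- tt >= -200 & tt < 0
  b <- apply(bc$trials[, , idx], c(1, 2), mean)
  expect_lt(max(abs(b)), 1e-12)
  # constant signal becomes all zero
  epc <- make_epochs(array(7, c(2, 2, 400)))
  expect_true(all(abs(baseline_correct(epc)$trials) < 1e-12))
  # baseline samples (1, 3), post-onset sample 10 -> 8
  ep3 <- make_epochs(array(c(1, 3, 10), c(1, 1, 3)), fs = 1000, t0_ms = -2)
  expect_equal(as.vector(baseline_correct(ep3, -2, 0)$trials), c(-1, 1, 8))
  expect_error(baseline_correct(ep, -300, 0), "baseline window")
})

test_that("trial averaging is the element-wise mean", {
  tr <- array(0, c(2, 2, 3))
  tr[1, , ] <- 2
  tr[2, , ] <- 4
  erp <- average_trials(make_epochs(tr, t0_ms = 0))
  expect_true(all(erp$erp == 3))
  # identical trials: average equals any one of them
  one <- matrix(rnorm(6), 2, 3)
  same <- array(0, c(4, 2, 3))
  for (i in 1:4) same[i, , ] <- one
  expect_equal(average_trials(make_epochs(same, t0_ms = 0))$erp, one,
               ignore_attr = TRUE)
})

test_that("preprocessing chain is invariant to trial order", {
  set.seed(3)
  ep <- make_epochs(array(rnorm(6 * 3 * 400), c(6, 3, 400)))
  pipeline <- function(e) average_trials(baseline_correct(rereference_average(e)))$erp
  perm <- ep
  perm$trials <- perm$trials[sample(6), , ]
  expect_equal(pipeline(ep), pipeline(perm), tolerance = 1e-12)
})

test_that("component amplitudes use half-open ms windows", {
  # fs = 1000: window 90-130 ms includes exactly samples 90..129
  erp <- structure(list(erp = matrix(seq_len(500) - 1, 1, 500,
                                     byrow = TRUE),
                        fs = 1000, t0_ms = 0, channels = "cz",
                        subject = "s", condition = "c"),
                   class = "erp_set")
  amps <- component_amplitudes(erp, data.frame(name = "P1", start_ms = 90,
                                               end_ms = 130))
  expect_equal(amps$amplitude, mean(90:129))
  # constant ERP: every window returns the constant
  erp$erp[] <- 5
  a <- component_amplitudes(erp)
  expect_true(all(a$amplitude == 5))
  expect_equal(nrow(a), 4)  # 4 default windows x 1 channel
  # linearity
  set.seed(4)
  e1 <- erp; e1$erp <- matrix(rnorm(500), 1)
  e2 <- erp; e2$erp <- matrix(rnorm(500), 1)
  ecomb <- erp; ecomb$erp <- 2 * e1$erp - 3 * e2$erp
  expect_equal(component_amplitudes(ecomb)$amplitude,
               2 * component_amplitudes(e1)$amplitude -
                 3 * component_amplitudes(e2)$amplitude,
               tolerance = 1e-12)
  expect_error(component_amplitudes(e1, data.frame(name = "x", start_ms = 600,
                                                   end_ms = 700)),
               "no samples")
})

amp_table <- function(values, channels, window = "P1") {
  do.call(rbind, lapply(seq_len(nrow(values)), function(i)
    data.frame(subject = sprintf("S%02d", i), channel = channels,
               window = window, amplitude = values[i, ])))
}

test_that("electrode selection matches a hand-computed paired t", {
  set.seed(5)
  n <- 20
  base <- matrix(rnorm(n * 3), n, 3)
  shift <- base + matrix(rnorm(n * 3, sd = 0.5), n, 3)
  shift[, 2] <- shift[, 2] + 5 * sd(base[, 2])  # strong effect on channel 2
  A <- amp_table(shift, c("a", "b", "c"))
  B <- amp_table(base, c("a", "b", "c"))
  sel <- select_electrodes(A, B, alpha = 0.05)
  expect_identical(sel$selected, "b")
  d <- shift[, 2] - base[, 2]
  t_hand <- mean(d) / (sd(d) / sqrt(n))
  row <- sel$per_window[sel$per_window$channel == "b", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-12)
})

test_that("identical amplitude tables select nothing (degenerate cells)", {
  set.seed(6)
  vals <- matrix(rnorm(12), 4, 3)
  A <- amp_table(vals, c("a", "b", "c"))
  expect_warning(sel <- select_electrodes(A, A, alpha = 0.05),
                 "zero-variance")
  expect_length(sel$selected, 0)
  expect_true(all(sel$per_window$degenerate))
  # mismatched grids error
  B <- A
  B$subject[1] <- "S99"
  expect_error(select_electrodes(A, B), "different subject")
})

test_that("region tally partitions the selected channels", {
  set.seed(7)
  vals <- matrix(rnorm(10 * 5), 10, 5)
  shift <- vals + matrix(rnorm(50, sd = 0.3), 10, 5)
  shift[, c(1, 2, 4)] <- shift[, c(1, 2, 4)] + 10
  chans <- c("F1", "F2", "T1", "P1", "O1")
  sel <- select_electrodes(amp_table(shift, chans), amp_table(vals, chans))
  rmap <- c(F1 = "F", F2 = "F", T1 = "T", P1 = "P", O1 = "O")
  tally <- region_tally(sel, rmap)
  expect_equal(sum(tally), length(sel$selected))
  expect_equal(unname(tally["F"]), 2L)
  expect_equal(unname(tally["P"]), 1L)
  expect_equal(unname(tally["T"]), 0L)
  # empty selection: all counts 0
  expect_warning(none <- select_electrodes(amp_table(vals, chans),
                                           amp_table(vals, chans)))
  expect_true(all(region_tally(none, rmap) == 0))
  # unmapped selected channel errors
  expect_error(region_tally(sel, rmap[-1]), "missing from region map")
})
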