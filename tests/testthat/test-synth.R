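test_that("ground-truth construction is valid and deterministic", {
  for (km in list(c(2, 2), c(3, 5), c(4, 8))) {
    tr <- build_ground_truth(K = km[1], M = km[2], seed = 7)
    expect_equal(sum(tr$pi), 1, tolerance = 1e-12)
    expect_equal(rowSums(tr$A), rep(1, km[1]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    for (k in seq_len(km[1])) {
      S <- tr$Sigma[k, , ]
      expect_equal(S, t(S), tolerance = 1e-12)
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
    offdiag <- function(k) mean(abs(erpstates:::upper_tri_vec(
      stats::cov2cor(tr$Sigma[k, , ]))))
    expect_lt(offdiag(tr$weak_state), offdiag(tr$strong_state))
  }
  tr1 <- build_ground_truth(K = 4, M = 8, seed = 42)
  tr2 <- build_ground_truth(K = 4, M = 8, seed = 42)
  expect_identical(tr1, tr2)
  expect_error(build_ground_truth(K = 1, M = 4), "K must be")
  expect_error(build_ground_truth(K = 4, M = 1), "M must be")
})

test_that("weak state is near-diagonal and strong state strongly coupled", {
  tr <- build_ground_truth(K = 4, M = 8, seed = 1)
  offdiag <- function(k) mean(abs(erpstates:::upper_tri_vec(
    stats::cov2cor(tr$Sigma[k, , ]))))
  expect_lt(offdiag(tr$weak_state), 0.15)
  expect_gt(offdiag(tr$strong_state), 0.5)
})

test_that("state sequences follow the biased chain", {
  tr <- build_ground_truth(K = 3, M = 2, seed = 5)
  # absorbing chain: identity transitions pin the initial state
  tr_abs <- tr
  tr_abs$A <- diag(3)
  tr_abs$pi <- c(1, 0, 0)
  p <- sample_state_sequence(tr_abs, "discomfort", 500, fs = 512,
                             split_ms = 100, seed = 3)
  expect_true(all(p == 1))

  # uniform chain with late bias 3: weak state occupancy rises after split
  tr2 <- build_ground_truth(K = 2, M = 2, seed = 5,
                            late_bias = c(comfort = 1, discomfort = 3),
                            early_bias = 1)
  tr2$A <- matrix(0.5, 2, 2)
  p <- sample_state_sequence(tr2, "discomfort", 20000, fs = 1000,
                             split_ms = 10000, seed = 9)
  early <- p[seq_len(10001)]
  late <- p[-seq_len(10001)]
  expect_gt(mean(late == tr2$weak_state), mean(early == tr2$weak_state))
  expect_equal(mean(early == tr2$weak_state), 0.5, tolerance = 0.05)
  expect_equal(mean(late == tr2$weak_state), 0.75, tolerance = 0.05)

  expect_error(sample_state_sequence(tr, "unknown", 100), "unknown condition")
})

test_that("homogeneous chain transition frequencies match A", {
  tr <- build_ground_truth(K = 3, M = 2, seed = 11, early_bias = 1,
                           late_bias = c(comfort = 1, discomfort = 1))
  p <- sample_state_sequence(tr, "comfort", 100000, fs = 512,
                             split_ms = 1100, seed = 2)
  emp <- matrix(0, 3, 3)
  for (t in 2:length(p)) emp[p[t - 1], p[t]] <- emp[p[t - 1], p[t]] + 1
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - tr$A)), 0.01)
})

test_that("subject data generation honours noise, effects and baseline", {
  tr <- build_ground_truth(K = 3, M = 4, seed = 2,
                           component_effect = list(channels = 3,
                                                   window_ms = c(90, 130),
                                                   shift = 2,
                                                   condition = "discomfort"))
  cfg <- synth_config(n_subjects = 2, n_trials = 3, fs = 256,
                      epoch_end_ms = 500, split_ms = 300, noise_sd = 0, seed = 1)
  p <- sample_state_sequence(tr, "comfort", 128, fs = 256, split_ms = 300,
                             seed = 4)
  # zero noise: every trial equals the template
  sd0 <- sample_subject_data(tr, p, cfg, "comfort", seed = 6)
  for (tr_i in 1:3)
    expect_equal(sd0$trials[tr_i, , ], sd0$template, tolerance = 1e-12)
  # pre-onset template is zero
  n_pre <- round(200 * 256 / 1000)
  expect_true(all(sd0$template[, seq_len(n_pre)] == 0))

  # component effect: +2 on channel 3 in 90-130 ms for discomfort only
  sdB <- sample_subject_data(tr, p, cfg, "discomfort", seed = 6)
  diff <- sdB$template - sd0$template
  tt <- erpstates:::sample_times(ncol(diff), 256, cfg$epoch_start_ms)
  in_win <- tt >= 90 & tt < 130
  expect_equal(mean(diff[3, in_win]), 2, tolerance = 1e-12)
  expect_true(all(abs(diff[-3, ]) < 1e-12))
  expect_true(all(abs(diff[3, !in_win]) < 1e-12))

  expect_error(sample_subject_data(tr, c(p, 99), cfg, "comfort"),
               "outside 1..K")
})

test_that("trial averaging noise shrinks as 1/sqrt(n_trials)", {
  tr <- build_ground_truth(K = 2, M = 2, seed = 3)
  cfg <- synth_config(n_subjects = 2, n_trials = 400, fs = 256,
                      epoch_end_ms = 300, split_ms = 200, noise_sd = 1, seed = 8)
  p <- sample_state_sequence(tr, "comfort", 77, fs = 256, split_ms = 200,
                             seed = 5)
  sd_ <- sample_subject_data(tr, p, cfg, "comfort", seed = 10)
  avg <- colMeans(aperm(sd_$trials, c(1, 2, 3)))
  resid <- avg - sd_$template
  expect_equal(sd(as.vector(resid)), 1 / sqrt(400), tolerance = 0.1)
})

test_that("generate_study is reproducible with correct shapes", {
  tr <- build_ground_truth(K = 3, M = 4, seed = 1)
  cfg <- synth_config(n_subjects = 2, n_trials = 3, fs = 128,
                      epoch_end_ms = 600, split_ms = 300, seed = 20)
  st1 <- generate_study(cfg, tr)
  st2 <- generate_study(cfg, tr)
  expect_identical(st1, st2)
  expect_length(st1$dataset$subjects, 2)
  T_total <- round(600 * 128 / 1000) + round(200 * 128 / 1000)
  for (s in st1$dataset$subjects) for (cond in c("comfort", "discomfort"))
    expect_equal(dim(st1$dataset$epochs[[s]][[cond]]$trials), c(3, 4, T_total))
})

test_that("huge subject_jitter recovers the group transition matrix", {
  tr <- build_ground_truth(K = 4, M = 4, seed = 6)
  cfg <- synth_config(n_subjects = 3, n_trials = 1, fs = 128,
                      epoch_end_ms = 400, split_ms = 200, subject_jitter = 1e6, seed = 30)
  st <- generate_study(cfg, tr)
  for (s in names(st$truth$A_subject))
    expect_lt(max(abs(st$truth$A_subject[[s]] - tr$A)), 0.01)
})

test_that("discomfort late bias raises ground-truth late weak-state occupancy", {
  tr <- build_ground_truth(K = 4, M = 4, seed = 9)
  cfg <- synth_config(n_subjects = 20, n_trials = 1, fs = 128,
                      epoch_end_ms = 3000, seed = 40)
  st <- generate_study(cfg, tr)
  occ <- sapply(c("comfort", "discomfort"), function(cond)
    mean(sapply(st$truth$paths, function(by_cond) {
      p <- by_cond[[cond]]
      po <- period_occupancy(p, 1100, 128, 0, 4)
      po$fraction_late[tr$weak_state]
    })))
  expect_gt(occ["discomfort"], occ["comfort"])
})
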