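test_that("all generators are deterministic in (truth, seed)", {
  sch <- light_schedule("LD")
  a1 <- simulate_activity(activity_truth(seed = 7), sch, days = 3)
  a2 <- simulate_activity(activity_truth(seed = 7), sch, days = 3)
  expect_identical(a1$values, a2$values)
  expect_false(identical(
    simulate_activity(activity_truth(seed = 8), sch, days = 3)$values,
    a1$values))
  ht <- hypnogram_truth(days = 0.25, seed = 7)
  expect_identical(simulate_hypnogram(ht)$labels, simulate_hypnogram(ht)$labels)
  hyp <- demo_hypnogram(12)
  e1 <- simulate_eeg_emg(hyp, fs = 250, seed = 7)
  e2 <- simulate_eeg_emg(hyp, fs = 250, seed = 7)
  expect_identical(e1$eeg$values, e2$eeg$values)
  expect_identical(e1$emg$values, e2$emg$values)
  pt <- photometry_truth(event_times_s = c(50), seed = 7)
  expect_identical(simulate_photometry(pt, 300, 10)$signal$values,
                   simulate_photometry(pt, 300, 10)$signal$values)
  ct <- cracm_truth(seed = 7)
  expect_identical(simulate_cracm(ct)$events, simulate_cracm(ct)$events)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulate_activity(activity_truth(seed = 1),
                                             light_schedule("DD"), days = 1))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("degenerate activity settings produce the forced series", {
  sch <- light_schedule("DD")
  flat <- simulate_activity(activity_truth(amplitude = 0, noise_sd = 0,
                                           mesor = 12), sch, days = 2)
  expect_equal(flat$values, rep(12, 576))
  pk <- simulate_activity(activity_truth(acrophase_h = 18, noise_sd = 0),
                          sch, days = 2)
  zt <- ((seq_along(pk$values) - 1) * 5 / 60) %% 24
  expect_true(all(zt[pk$values == max(pk$values)] == 18))
  expect_error(simulate_activity(activity_truth(), sch, days = 0), ">= 1")
  expect_error(activity_truth(period_h = -1), "positive")
})

test_that("light masking multiplies lights-on bins only", {
  sch <- light_schedule("LD")
  base <- simulate_activity(activity_truth(noise_sd = 0, masking_gain = 1),
                            sch, days = 1)
  masked <- simulate_activity(activity_truth(noise_sd = 0, masking_gain = 0.4),
                              sch, days = 1)
  zt <- ((seq_along(base$values) - 1) * 5 / 60) %% 24
  light <- zt < 12
  expect_equal(masked$values[light], 0.4 * base$values[light])
  expect_equal(masked$values[!light], base$values[!light])
})

test_that("arrhythmic surrogates keep the marginal but lose the rhythm", {
  sch <- light_schedule("DD")
  rhyth <- simulate_activity(activity_truth(noise_sd = 0, seed = 3),
                             sch, days = 10)
  arr <- simulate_activity(activity_truth(noise_sd = 0, arrhythmic = TRUE,
                                          seed = 3), sch, days = 10)
  expect_equal(sort(arr$values), sort(rhyth$values))
  qp_r <- select_circadian_period(chisq_periodogram(rhyth))
  qp_a <- select_circadian_period(chisq_periodogram(arr, bonferroni = TRUE))
  expect_gt(qp_r$amplitude_above_sig, 0)
  expect_false(qp_a$significant)   # matched-power null stays below the line
  expect_lt(qp_a$qp, 0.25 * qp_r$qp)
})

test_that("hypnogram truth validates transition matrices", {
  bad <- transition_matrix(); bad[1, 1] <- 0.5
  expect_error(hypnogram_truth(p_dark = bad), "sum to 1")
  expect_error(transition_matrix(wake_dur_s = 5), "at least one epoch")
})

test_that("an absorbing Wake state yields an all-Wake hypnogram", {
  P <- diag(3); dimnames(P) <- list(c("Wake", "NREM", "REM"),
                                    c("Wake", "NREM", "REM"))
  hyp <- simulate_hypnogram(hypnogram_truth(p_dark = P, p_light = P,
                                            days = 0.1, seed = 1))
  expect_true(all(hyp$labels == "Wake"))
})

test_that("phase-symmetric truth gives a D/L wake ratio near 1", {
  P <- transition_matrix(wake_dur_s = 90)
  ratios <- vapply(1:20, function(s) {
    hyp <- simulate_hypnogram(hypnogram_truth(p_dark = P, p_light = P,
                                              days = 20, seed = 40 + s))
    dl_ratio(hyp, light_schedule("DD"))[["Wake"]]
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("episode durations converge to the truth means", {
  hyp <- simulate_hypnogram(hypnogram_truth(
    p_dark = transition_matrix(wake_dur_s = 120),
    p_light = transition_matrix(wake_dur_s = 120), days = 30, seed = 13))
  ep <- detect_episodes(hyp)
  mean_wake <- mean(ep$duration_s[ep$state == "Wake"])
  expect_equal(mean_wake, 120, tolerance = 0.1 * 120)
})

test_that("NREM epochs are delta-dominated in the generated EEG", {
  hyp <- demo_hypnogram(40)
  sig <- simulate_eeg_emg(hyp, fs = 250, seed = 21)
  b <- spectral_bands(sig$eeg, hyp, epoch_s = 10)
  nrem <- b[b$state == "NREM" & b$included, ]
  bn <- eeg_bands()$band
  dom <- apply(nrem[, bn], 1, function(r) which.max(r) == 1)
  expect_gte(mean(dom), 0.95)
})

test_that("EEG/EMG generation enforces the sampling-rate precondition", {
  hyp <- demo_hypnogram(12)
  expect_error(simulate_eeg_emg(hyp, fs = 200), "too low")
  prof <- eeg_state_profiles()
  for (s in names(prof)) prof[[s]]$emg_amp <- 0
  sig <- simulate_eeg_emg(hyp, profiles = prof, fs = 250, seed = 2)
  f <- compute_epoch_features(sig$eeg, sig$emg)
  expect_equal(f$emg_rms, rep(0, nrow(f)))
})

test_that("photometry generator honors its closed forms", {
  tru <- photometry_truth(noise_sd = 0, seed = 1)
  sess <- simulate_photometry(tru, 600, fs = 5)
  t <- (seq_along(sess$signal$values) - 1) / 5
  expected <- (30 * exp(-t / 1800) + 10 * exp(-t / 120) + 60) * 1
  expect_equal(sess$signal$values, expected)   # no events, no noise
  tru1 <- photometry_truth(noise_sd = 0, event_times_s = 100,
                           kernel_rise_s = 1, kernel_decay_s = 4, seed = 1)
  s1 <- simulate_photometry(tru1, 600, fs = 5)
  resid <- s1$signal$values - expected
  tpk <- t[which.max(resid)]
  expect_true(tpk >= 100 && tpk <= 105)        # within kernel support
  expect_error(photometry_truth(kernel_decay_s = -1), "positive")
})

test_that("evoked events obey the binomial law over many trials", {
  tr <- cracm_truth(p_evoked = 0.9778, n_trials = 1000,
                    baseline_rate_hz = 0, seed = 31)
  p_hat <- response_probability(simulate_cracm(tr)) / 100
  expect_lt(abs(p_hat - 0.9778), 3 * sqrt(0.9778 * (1 - 0.9778) / 1000))
  det <- simulate_cracm(cracm_truth(p_evoked = 1, latency_jitter_ms = 0,
                                    baseline_rate_hz = 0, n_trials = 10,
                                    seed = 1))
  on <- det$protocol$pulse_onsets_s
  expect_equal(nrow(det$events), 10)           # exactly one event per pulse
  expect_equal(det$events$t_s - on, rep(0.010, 10), tolerance = 1e-12)
})

test_that("generated noise moments match the stated parameters", {
  devs <- vapply(1:20, function(s) {
    ts <- simulate_activity(activity_truth(amplitude = 0, mesor = 100,
                                           noise_sd = 5, seed = 60 + s),
                            light_schedule("DD"), days = 2)
    sd(ts$values)
  }, 0)
  expect_equal(mean(devs), 5, tolerance = 0.2)
})

test_that("generator output feeds every analysis stage without coercion", {
  sch <- light_schedule("DD")
  ts <- simulate_activity(activity_truth(seed = 3), sch, days = 10)
  expect_s3_class(chisq_periodogram(ts), "chisq_periodogram")
  hyp <- simulate_hypnogram(hypnogram_truth(days = 1 / 12, seed = 3))
  sig <- simulate_eeg_emg(hyp, fs = 250, seed = 3)
  expect_s3_class(score_epochs(compute_epoch_features(sig$eeg, sig$emg)),
                  "hypnogram")
  sess <- simulate_photometry(photometry_truth(seed = 3), 300, 10)
  expect_s3_class(standardize(dff(downsample(sess$signal, 1),
                                  fit_bleach_baseline(downsample(sess$signal, 1)))),
                  "regts")
  expect_s3_class(cracm_connectivity(simulate_cracm(cracm_truth(seed = 3))),
                  "connectivity_result")
})
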