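test_that("the event detector finds rendered IPSCs and merges close peaks", {
  fs <- 5000
  t <- (0:(fs / 2)) / fs
  one <- regts(100 * chronophys:::doe_kernel(t - 0.05, 0.001, 0.010), 1 / fs)
  ev <- detect_events(one, threshold_pA = 20)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude_pA - 100) / 100, 0.05)
  expect_equal(nrow(detect_events(one, threshold_pA = 150)), 0)
  expect_equal(nrow(detect_events(regts(rep(0, 1000), 1 / fs), 20)), 0)
  two <- regts(one$values +
                 100 * chronophys:::doe_kernel(t - 0.055, 0.001, 0.010), 1 / fs)
  expect_equal(nrow(detect_events(two, 20, min_interval_ms = 20)), 1)  # merged
  expect_equal(nrow(detect_events(two, 20, min_interval_ms = 2)), 2)
})

test_that("response probability counts pulses with events in (onset, onset+50ms]", {
  proto <- stim_protocol("single", n_trials = 4, inter_trial_s = 10)
  on <- proto$pulse_onsets_s
  hit_all <- stim_session(proto, data.frame(t_s = on + 0.01,
                                            amplitude_pA = 100))
  expect_equal(response_probability(hit_all), 100)
  expect_true(classify_connected(response_probability(hit_all)))
  none <- stim_session(proto, data.frame(t_s = numeric(),
                                         amplitude_pA = numeric()))
  expect_equal(response_probability(none), 0)
  # an event exactly at the onset is baseline, not response
  at_onset <- stim_session(proto, data.frame(t_s = on, amplitude_pA = 100))
  expect_equal(response_probability(at_onset), 0)
  expect_equal(baseline_probability(at_onset), 100)
})

test_that("response probability is binomial across seeds", {
  probs <- vapply(1:100, function(s) {
    tr <- cracm_truth(p_evoked = 0.5, n_trials = 30, baseline_rate_hz = 0,
                      seed = s)
    response_probability(simulate_cracm(tr))
  }, 0)
  expect_equal(mean(probs), 50, tolerance = 3)        # sem = 9.1/sqrt(100)
  expect_equal(sd(probs), 100 * sqrt(0.25 / 30), tolerance = 2)
})

test_that("baseline probability matches the Poisson closed form", {
  lam <- 4; w <- 0.05
  expected <- 100 * (1 - exp(-lam * w))               # 18.1%
  probs <- vapply(1:60, function(s) {
    tr <- cracm_truth(p_evoked = 0, n_trials = 30, baseline_rate_hz = lam,
                      seed = 700 + s)
    baseline_probability(simulate_cracm(tr))
  }, 0)
  expect_equal(mean(probs), expected, tolerance = 3)
  expect_equal(baseline_probability(
    simulate_cracm(cracm_truth(p_evoked = 0, baseline_rate_hz = 0))), 0)
  tight <- stim_protocol("single", n_trials = 3, inter_trial_s = 0.08)
  expect_error(baseline_probability(
    stim_session(tight, data.frame(t_s = 1, amplitude_pA = 10))), "overlap")
})

test_that("the connected criterion is strict at 50%", {
  expect_true(classify_connected(97.78))
  expect_false(classify_connected(21.08))
  expect_false(classify_connected(50.00))
  expect_error(classify_connected(120), "\\[0, 100\\]")
})

test_that("trace latency hits the analytic 5%-rise point within one sample", {
  fs <- 5000
  tr <- cracm_truth(p_evoked = 1, latency_mean_ms = 10,
                    latency_jitter_ms = 0, baseline_rate_hz = 0,
                    n_trials = 5, seed = 1)
  sess <- simulate_cracm(tr, render = TRUE, fs = fs)
  lat <- evoked_latency(sess)
  expect_false(lat$onset_based)
  analytic <- 10 + analytic_rise5_ms(1, 10)
  expect_true(all(abs(lat$latency_ms - analytic) <= 1000 / fs + 1e-9))
})

test_that("jittered latencies average to the generator mean", {
  tr <- cracm_truth(p_evoked = 1, latency_mean_ms = 10,
                    latency_jitter_ms = 1, baseline_rate_hz = 0,
                    n_trials = 100, seed = 2)
  lat <- evoked_latency(simulate_cracm(tr))
  expect_true(lat$onset_based)
  expect_lt(abs(lat$mean_ms - 10), 3 * 1 / sqrt(100))
  none <- simulate_cracm(cracm_truth(p_evoked = 0, baseline_rate_hz = 0,
                                     n_trials = 5))
  expect_warning(l0 <- evoked_latency(none), "undefined")
  expect_equal(l0$n_responsive, 0L)
})

test_that("onset- and rise-based latencies differ by a kernel constant", {
  fs <- 10000
  tr <- cracm_truth(p_evoked = 1, latency_mean_ms = 12,
                    latency_jitter_ms = 0.5, baseline_rate_hz = 0,
                    n_trials = 20, seed = 3)
  sess <- simulate_cracm(tr, render = TRUE, fs = fs)
  rise <- evoked_latency(sess)$latency_ms
  sess_noTrace <- sess; sess_noTrace$trace <- NULL
  onset <- evoked_latency(sess_noTrace)$latency_ms
  d <- rise - onset
  expect_lt(max(d) - min(d), 2 * 1000 / fs + 1e-9)  # constant up to sampling
})

test_that("amplitude summaries average first evoked events", {
  proto <- stim_protocol("single", n_trials = 3)
  on <- proto$pulse_onsets_s
  s <- stim_session(proto, data.frame(t_s = on + 0.005,
                                      amplitude_pA = c(100, 100, 100)))
  a <- amplitude_summary(s)
  expect_equal(a$mean_pA, 100); expect_equal(a$sem_pA, 0)
  tr <- cracm_truth(p_evoked = 1, amp_mean_pa = 107.2, amp_sd_pa = 20,
                    baseline_rate_hz = 0, n_trials = 100, seed = 4)
  a2 <- amplitude_summary(simulate_cracm(tr))
  expect_lt(abs(a2$mean_pA - 107.2), 3 * 20 / sqrt(100))
  one <- stim_session(stim_protocol("single", n_trials = 1),
                      data.frame(t_s = 1.005, amplitude_pA = 80))
  expect_true(is.na(amplitude_summary(one)$sem_pA))
})

test_that("unconnected cells with sub-criterion baseline rates never classify connected", {
  # lambda chosen so the per-window event probability is ~18% (< 20%);
  # the binomial tail above 50% of 30 trials is then < 1e-3
  flags <- vapply(1:200, function(s) {
    tr <- cracm_truth(connected = FALSE, p_evoked = 0, baseline_rate_hz = 4,
                      n_trials = 30, seed = 900 + s)
    classify_connected(response_probability(simulate_cracm(tr)))
  }, TRUE)
  expect_false(any(flags))
})

test_that("estimated evoked probability is unbiased at 30 trials", {
  p <- 0.7
  est <- vapply(1:200, function(s) {
    tr <- cracm_truth(p_evoked = p, baseline_rate_hz = 0, n_trials = 30,
                      seed = 1200 + s)
    response_probability(simulate_cracm(tr)) / 100
  }, 0)
  sem <- sqrt(p * (1 - p) / 30) / sqrt(200)
  expect_lt(abs(mean(est) - p), 2 * sqrt(p * (1 - p) / 30))
  expect_lt(abs(mean(est) - p), 4 * sem)  # tighter Monte-Carlo check
})

test_that("the full connectivity summary assembles all statistics", {
  tr <- cracm_truth(p_evoked = 0.9778, n_trials = 30, baseline_rate_hz = 4.2,
                    latency_mean_ms = 9.97, seed = 5)
  res <- cracm_connectivity(simulate_cracm(tr))
  expect_true(res$connected)
  expect_gt(res$response_prob, 50)
  expect_lt(res$baseline_prob, 50)
  expect_true(is.finite(res$latency$mean_ms))
  expect_true(is.finite(res$amplitude$mean_pA))
})
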