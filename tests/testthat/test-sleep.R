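test_that("epoch features compute EMG RMS and spectral band powers", {
  fs <- 250; dur <- 120
  eeg <- sine_ts(3, dur, fs)
  emg <- regts(rep(-2, dur * fs), 1 / fs)
  f <- compute_epoch_features(eeg, emg, epoch_s = 10)
  expect_equal(nrow(f), 12)
  expect_equal(f$emg_rms, rep(2, 12))           # RMS of a constant is |c|
  expect_true(all(f$theta_delta_ratio < 0.1))   # 3-Hz sine is delta
  f7 <- compute_epoch_features(sine_ts(7, dur, fs), emg, epoch_s = 10)
  expect_true(all(f7$theta_delta_ratio > 10))   # 7-Hz sine is theta
  expect_error(compute_epoch_features(eeg, regts(rnorm(10), 1 / fs)), "span")
})

test_that("scoring rules follow the EMG -> delta -> theta:delta cascade", {
  n <- 400
  f <- data.frame(epoch = 1:n, emg_rms = rep(0, n),
                  delta_power = rep(50, n), theta_power = rep(10, n),
                  theta_delta_ratio = rep(0.2, n))
  attr(f, "epoch_s") <- 10
  th <- list(emg = 1, delta = 10, theta_delta = 1)
  hyp <- score_epochs(f, th)
  expect_true(all(hyp$labels == "NREM"))  # silent EMG + high delta
  # low delta + high ratio scores REM, but only after NREM
  f2 <- f
  f2$emg_rms[1:50] <- 5                         # wake run
  f2$delta_power[51:60] <- 1; f2$theta_delta_ratio[51:60] <- 5
  hyp2 <- score_epochs(f2, th)
  expect_equal(hyp2$labels[51], "Wake")         # REM straight out of wake: inadmissible
  f3 <- f
  f3$delta_power[54:60] <- 1; f3$theta_delta_ratio[54:60] <- 5
  hyp3 <- score_epochs(f3, th)
  expect_equal(hyp3$labels[54], "REM")          # NREM within 3 epochs: admissible
})

test_that("automatic thresholds recover generator states on separable features", {
  accs <- vapply(1:3, function(s) {
    hyp <- simulate_hypnogram(hypnogram_truth(days = 1 / 12, seed = s))
    sig <- simulate_eeg_emg(hyp, fs = 250, seed = s)
    f <- compute_epoch_features(sig$eeg, sig$emg)
    mean(score_epochs(f)$labels == hyp$labels)
  }, 0)
  expect_true(all(accs >= 0.95))
})

test_that("state amounts tally minutes per window and conserve time", {
  sch <- light_schedule("DD")
  all_wake <- hypnogram(rep("Wake", 8640), 10, "2024-01-01 07:00:00")
  am <- state_amounts(all_wake, sch, "hourly")
  expect_true(all(am$wake_min == 60))
  alt <- hypnogram(rep(c("Wake", "NREM"), 4320), 10, "2024-01-01 07:00:00")
  am2 <- state_amounts(alt, sch, "hourly")
  expect_true(all(am2$wake_min == 30) && all(am2$nrem_min == 30))
  # conservation with artifacts present, against direct label counting
  set.seed(8)
  lab <- sample(c("Wake", "NREM", "REM", "Artifact"), 8640, TRUE)
  hyp <- hypnogram(lab, 10, "2024-01-01 07:00:00")
  am3 <- state_amounts(hyp, sch, "hourly")
  expect_equal(am3$wake_min + am3$nrem_min + am3$rem_min + am3$artifact_min,
               am3$window_min)
  expect_equal(sum(am3$wake_min), sum(lab == "Wake") * 10 / 60)
})

test_that("dark/light ratio is 1 for balanced records and flags empty phases", {
  lab <- rep(c("Wake", "NREM"), 4320)
  hyp <- hypnogram(lab, 10, "2024-01-01 07:00:00")   # starts at ZT0
  r <- dl_ratio(hyp, light_schedule("DD"))
  expect_equal(unname(r[c("Wake", "NREM")]), c(1, 1))
  lab2 <- c(rep("Wake", 4320), rep("NREM", 4320))    # REM absent, NREM only in dark
  expect_warning(r2 <- dl_ratio(hypnogram(lab2, 10, "2024-01-01 07:00:00"),
                                light_schedule("DD")), "infinite")
  expect_true(is.infinite(r2[["NREM"]]))
})

test_that("dark-biased generator yields the designed wake D/L ratio", {
  # dark wake duration 132 s vs light 44 s makes the stationary wake
  # occupancy ratio exactly 2 under the default exit structure
  ratios <- vapply(1:20, function(s) {
    hyp <- simulate_hypnogram(hypnogram_truth(days = 20, seed = 300 + s))
    dl_ratio(hyp, light_schedule("DD"))[["Wake"]]
  }, 0)
  expect_equal(mean(ratios), 2.0, tolerance = 0.1)
})

test_that("episodes are maximal runs that reconstruct the hypnogram", {
  hyp <- hypnogram(c("Wake", "Wake", "NREM", "NREM", "NREM", "REM"), 10)
  ep <- detect_episodes(hyp)
  expect_equal(ep$state, c("Wake", "NREM", "REM"))
  expect_equal(ep$duration_s, c(20, 30, 10))
  expect_equal(detect_episodes(hypnogram(rep("Wake", 50), 10))$duration_s, 500)
  set.seed(4)
  lab <- sample(c("Wake", "NREM", "REM", "Artifact"), 2000, TRUE)
  hyp2 <- hypnogram(lab, 10)
  ep2 <- detect_episodes(hyp2)
  expect_equal(sum(ep2$duration_s), 2000 * 10)
  expect_identical(rep(ep2$state, ep2$duration_s / 10), lab)  # round trip
})

test_that("episode histogram reproduces the hand-computed worked example", {
  ep <- data.frame(state = "NREM", start_s = c(0, 100, 300),
                   duration_s = c(20, 50, 100))
  h <- episode_histogram(ep, "NREM")
  expect_equal(h$count, c(1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(h$time_weighted_pct[1:3], 100 * c(20, 50, 100) / 170,
               tolerance = 1e-9)
  expect_equal(round(h$time_weighted_pct[1:3], 2), c(11.76, 29.41, 58.82))
  expect_equal(sum(h$time_weighted_pct), 100, tolerance = 1e-9)
  h2 <- episode_histogram(data.frame(state = "REM", duration_s = 3000), "REM")
  expect_equal(h2$count, c(0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(h2$time_weighted_pct[8], 100)
  h3 <- episode_histogram(ep, "Wake")          # absent state
  expect_equal(sum(h3$count), 0)
  expect_true(all(is.na(h3$time_weighted_pct)))
  # 30 s is inclusive in the first bin; 40 s opens the second
  h4 <- episode_histogram(data.frame(state = "Wake",
                                     duration_s = c(30, 40)), "Wake")
  expect_equal(h4$count[1:2], c(1, 1))
})

test_that("band powers partition total 0.5-120 Hz power and localize sines", {
  fs <- 250
  hyp <- hypnogram(rep("NREM", 12), epoch_s = 10)
  b3 <- spectral_bands(sine_ts(3, 120, fs), hyp)
  inc <- b3[b3$included, ]
  bn <- eeg_bands()$band
  expect_equal(unname(rowSums(inc[, bn])), inc$total_power, tolerance = 1e-9)
  expect_true(all(inc$delta / inc$total_power >= 0.90))
  b40 <- spectral_bands(sine_ts(40, 120, fs), hyp)
  inc40 <- b40[b40$included, ]
  expect_true(all(inc40$low_gamma > inc40[, setdiff(bn, "low_gamma")]))
  expect_error(spectral_bands(sine_ts(3, 120, 100), hyp), "240")
})

test_that("artifact and transition epochs are excluded from spectra", {
  fs <- 250
  lab <- c(rep("NREM", 6), "Artifact", rep("Wake", 5))
  hyp <- hypnogram(lab, epoch_s = 10)
  b <- spectral_bands(sine_ts(3, 120, fs), hyp, epoch_s = 5)
  expect_equal(nrow(b), 24)                     # 10-s labels expand to 5-s epochs
  expect_true(all(!b$included[b$state == "Artifact"]))
  # epochs flanking the artifact are state transitions
  expect_false(b$included[12]); expect_false(b$included[15])
  expect_true(b$included[11])
  expect_true(all(is.na(b$delta[!b$included])))
})

test_that("band normalization returns percentages of the reference", {
  fs <- 250
  hyp <- hypnogram(rep("NREM", 12), epoch_s = 10)
  b <- spectral_bands(sine_ts(3, 120, fs), hyp)
  bn <- eeg_bands()$band
  self_ref <- normalize_bands(b, b)
  expect_equal(mean(self_ref$delta[self_ref$included]), 100, tolerance = 1e-9)
  doubled <- b; for (col in bn) doubled[[col]] <- 2 * b[[col]]
  expect_equal(mean(normalize_bands(doubled, b)$delta[b$included]), 200,
               tolerance = 1e-9)
  per24 <- normalize_bands(b, "per24h")
  expect_equal(mean(per24$delta[per24$included]), 100, tolerance = 1e-9)
})

test_that("the 20% wake-artifact rule is strict", {
  mk <- function(pct) hypnogram(c(rep("Artifact", pct), rep("Wake", 100 - pct)), 10)
  expect_true(artifact_exclusion(mk(19)))
  expect_true(artifact_exclusion(mk(20)))   # exactly 20%: kept ("more than")
  expect_false(artifact_exclusion(mk(21)))
})
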