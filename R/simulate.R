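# Seeded generators for every input modality. Each generator is a pure
# function of (truth, seed): randomness flows through one local RNG stream
# (see with_seed) and never touches global state, so the same seed always
# reproduces the identical output.

#' Ground truth for a synthetic activity / temperature record
#'
#' Parameters of a sinusoid-plus-noise circadian record: a cosine of known
#' period and acrophase riding on a mesor, Gaussian bin noise, optional
#' multiplicative light masking, and an optional arrhythmic switch that
#' replaces the cosine with a phase-randomized surrogate of matched
#' marginal distribution (a matched-power null for the periodogram).
#'
#' @param period_h rhythm period in hours (> 0).
#' @param acrophase_h peak position of the cosine, in ZT hours.
#' @param mesor,amplitude mean level and cosine amplitude, counts/bin.
#' @param noise_sd Gaussian noise SD, counts/bin.
#' @param masking_gain multiplier applied to bins while lights are on
#'   (1 = no masking; < 1 suppresses activity in the light).
#' @param arrhythmic if `TRUE`, shuffle the rhythmic component across bins.
#' @param seed integer RNG seed.
#' @return list of class `"activity_truth"`.
#' @export
activity_truth <- function(period_h = 24, acrophase_h = 18, mesor = 20,
                           amplitude = 15, noise_sd = 5, masking_gain = 1,
                           arrhythmic = FALSE, seed = 1L) {
  if (period_h <= 0) stop("'period_h' must be positive")
  if (amplitude < 0 || noise_sd < 0) stop("'amplitude' and 'noise_sd' must be >= 0")
  structure(list(period_h = period_h, acrophase_h = acrophase_h,
                 mesor = mesor, amplitude = amplitude, noise_sd = noise_sd,
                 masking_gain = masking_gain, arrhythmic = isTRUE(arrhythmic),
                 seed = as.integer(seed)),
            class = "activity_truth")
}

#' Simulate a binned activity or temperature record
#'
#' Generates `days` of data at `bin_min` bins starting at ZT0 (lights-on) of
#' day 1: `max(0, mesor + amplitude * cos(2 * pi * (zt - acrophase) /
#' period) + noise)`, multiplied by `masking_gain` in lights-on bins. With
#' `arrhythmic = TRUE` the cosine term is replaced by a shuffled-bin
#' surrogate with the same marginal distribution.
#'
#' @param truth an [activity_truth()].
#' @param schedule a [light_schedule()].
#' @param days number of simulated days (>= 1).
#' @param bin_min bin width in minutes; must divide 24 h.
#' @param units unit label for the returned series.
#' @return a [regts()] of length `days * 24 * 60 / bin_min`.
#' @export
simulate_activity <- function(truth, schedule = light_schedule("DD"),
                              days = 10, bin_min = 5, units = "counts") {
  stopifnot(inherits(truth, "activity_truth"))
  if (days < 1) stop("'days' must be >= 1")
  if ((24 * 60) %% bin_min != 0) stop("'bin_min' must divide 24 h")
  n <- days * 24 * 60 / bin_min
  zt <- (seq_len(n) - 1) * bin_min / 60
  rhythm <- truth$amplitude *
    cos(2 * pi * (zt - truth$acrophase_h) / truth$period_h)
  with_seed(truth$seed, {
    if (truth$arrhythmic) rhythm <- sample(rhythm)
    x <- truth$mesor + rhythm +
      if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0
  })
  x <- pmax(0, x)
  x[is_light(schedule, zt)] <- x[is_light(schedule, zt)] * truth$masking_gain
  start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
    schedule$lights_on * 3600
  regts(x, bin_min * 60, start, units)
}

#' Ground truth for a synthetic hypnogram
#'
#' A circadian-modulated Markov process over vigilance states: one epoch
#' transition matrix for the (subjective) dark phase (ZT 12-24) and one for
#' the light phase (ZT 0-12). The mean episode duration of state s under a
#' matrix P is `epoch_s / (1 - P[s, s])` seconds.
#'
#' @param p_dark,p_light row-stochastic transition matrices with identical
#'   dimnames over the state set (default built by
#'   [transition_matrix()] with mouse-like episode durations and a 2:1
#'   dark:light wake occupancy bias).
#' @param epoch_s epoch length in seconds (default 10).
#' @param days simulated days.
#' @param seed integer RNG seed.
#' @return list of class `"hypnogram_truth"`.
#' @export
hypnogram_truth <- function(p_dark = transition_matrix(wake_dur_s = 132),
                            p_light = transition_matrix(wake_dur_s = 44),
                            epoch_s = 10, days = 2, seed = 1L) {
  for (P in list(p_dark, p_light)) {
    if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0) ||
        any(abs(rowSums(P) - 1) > 1e-9))
      stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (!identical(dimnames(p_dark), dimnames(p_light)))
    stop("phase matrices must share state names")
  structure(list(p_dark = p_dark, p_light = p_light, epoch_s = epoch_s,
                 days = days, seed = as.integer(seed)),
            class = "hypnogram_truth")
}

#' Build a vigilance-state transition matrix from episode durations
#'
#' Constructs a Wake/NREM/REM epoch transition matrix with self-transition
#' probabilities `1 - epoch_s / duration` and a fixed exit structure: Wake
#' exits to NREM; NREM exits to Wake (probability `nrem_to_wake`) or REM;
#' REM exits to Wake. Under this structure the stationary wake occupancy is
#' `d_W / (d_W + d_N + (1 - nrem_to_wake) * d_R)` with durations in epochs,
#' which makes occupancy ratios between phases exactly controllable.
#'
#' @param wake_dur_s,nrem_dur_s,rem_dur_s mean episode durations, seconds.
#' @param nrem_to_wake probability that an NREM exit goes to Wake.
#' @param epoch_s epoch length in seconds.
#' @return 3x3 row-stochastic matrix with dimnames Wake/NREM/REM.
#' @export
transition_matrix <- function(wake_dur_s = 120, nrem_dur_s = 120,
                              rem_dur_s = 60, nrem_to_wake = 0.8,
                              epoch_s = 10) {
  d <- c(wake_dur_s, nrem_dur_s, rem_dur_s) / epoch_s
  if (any(d < 1)) stop("mean durations must be at least one epoch")
  states <- c("Wake", "NREM", "REM")
  P <- matrix(0, 3, 3, dimnames = list(states, states))
  ex <- 1 / d                      # per-epoch exit probabilities
  P["Wake", ] <- c(1 - ex[1], ex[1], 0)
  P["NREM", ] <- c(ex[2] * nrem_to_wake, 1 - ex[2], ex[2] * (1 - nrem_to_wake))
  P["REM", ]  <- c(ex[3], 0, 1 - ex[3])
  P
}

#' Simulate a hypnogram from a phase-dependent Markov process
#'
#' Draws per-epoch vigilance labels from the dark-phase matrix during
#' (subjective) ZT 12-24 and the light-phase matrix during ZT 0-12; the
#' record starts in Wake at ZT0.
#'
#' @param truth a [hypnogram_truth()].
#' @param schedule a [light_schedule()] anchoring ZT.
#' @return a [hypnogram()].
#' @export
simulate_hypnogram <- function(truth, schedule = light_schedule("DD")) {
  stopifnot(inherits(truth, "hypnogram_truth"))
  states <- rownames(truth$p_dark)
  n <- as.integer(truth$days * 86400 / truth$epoch_s)
  zt <- ((seq_len(n) - 1) * truth$epoch_s / 3600) %% 24
  dark <- zt >= 12
  cum_d <- t(apply(truth$p_dark, 1, cumsum))
  cum_l <- t(apply(truth$p_light, 1, cumsum))
  lab <- integer(n)
  with_seed(truth$seed, {
    u <- stats::runif(n)
    s <- 1L
    for (i in seq_len(n)) {
      cm <- if (dark[i]) cum_d else cum_l
      s <- which(u[i] <= cm[s, ])[1L]
      lab[i] <- s
    }
  })
  start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
    schedule$lights_on * 3600
  hypnogram(states[lab], epoch_s = truth$epoch_s, start = start)
}

#' Per-state EEG band-power and EMG amplitude profiles
#'
#' Default generative profiles: NREM dominated by delta, REM by theta with
#' low muscle tone, Wake with broadband EEG and high EMG. Values are
#' variances (power) per band in arbitrary uV^2 units.
#'
#' @return named list per state with elements `bands` (named vector over
#'   the six canonical bands) and `emg_amp`.
#' @export
eeg_state_profiles <- function() {
  b <- function(delta, theta, sigma, beta, low_gamma, high_gamma)
    c(delta = delta, theta = theta, sigma = sigma, beta = beta,
      low_gamma = low_gamma, high_gamma = high_gamma)
  list(
    Wake = list(bands = b(1.5, 2.0, 0.8, 0.8, 0.5, 0.3), emg_amp = 3.0),
    NREM = list(bands = b(8.0, 1.5, 1.0, 0.5, 0.2, 0.1), emg_amp = 0.5),
    REM  = list(bands = b(0.8, 4.0, 0.5, 0.4, 0.3, 0.2), emg_amp = 0.15),
    Artifact = list(bands = b(4.5, 6.0, 2.4, 2.4, 1.5, 0.9), emg_amp = 8.0))
}

# band-limited unit-variance Gaussian noise via FFT masking
band_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  W[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Simulate state-dependent EEG and EMG signals from a hypnogram
#'
#' The EEG is a sum of band-limited Gaussian noise components, one per
#' canonical band, each scaled epoch-by-epoch to the generating state's
#' band-power profile; the EMG is white noise scaled by the state's muscle
#' tone. State boundaries align exactly with hypnogram epochs. No 1/f
#' shaping beyond the band mixture is applied.
#'
#' @param hyp a [hypnogram()].
#' @param profiles per-state profiles as from [eeg_state_profiles()].
#' @param fs sampling rate in Hz; must be at least twice the top band edge
#'   (240 Hz for the default 120-Hz limit).
#' @param seed integer RNG seed.
#' @return list with [regts()] elements `eeg` and `emg`.
#' @export
simulate_eeg_emg <- function(hyp, profiles = eeg_state_profiles(), fs = 500,
                             seed = 1L) {
  stopifnot(inherits(hyp, "hypnogram"))
  bands <- eeg_bands()
  if (fs < 2 * max(bands$hi))
    stop(sprintf("fs = %g Hz too low for bands up to %g Hz (need >= %g)",
                 fs, max(bands$hi), 2 * max(bands$hi)))
  spe <- hyp$epoch_s * fs
  if (abs(spe - round(spe)) > 1e-9) stop("fs * epoch_s must be integer")
  spe <- as.integer(round(spe))
  n <- spe * length(hyp$labels)
  lab <- hyp$labels
  miss <- setdiff(unique(lab), names(profiles))
  if (length(miss)) stop("no profile for state(s): ", paste(miss, collapse = ", "))
  with_seed(seed, {
    eeg <- numeric(n)
    for (b in seq_len(nrow(bands))) {
      pw <- vapply(lab, function(s) profiles[[s]]$bands[[bands$band[b]]], 0)
      eeg <- eeg + band_noise(n, fs, bands$lo[b], bands$hi[b]) *
        rep(sqrt(pw), each = spe)
    }
    amp <- vapply(lab, function(s) profiles[[s]]$emg_amp, 0)
    emg <- stats::rnorm(n) * rep(amp, each = spe)
  })
  list(eeg = regts(eeg, 1 / fs, hyp$start, "uV"),
       emg = regts(emg, 1 / fs, hyp$start, "uV"))
}

#' Ground truth for a synthetic photometry session
#'
#' Generative model: a two-exponential photobleaching baseline multiplies a
#' tonic fluorescence level plus a train of calcium-transient kernels
#' (difference of exponentials), with additive Gaussian noise and optional
#' movement-artifact bumps shared sample-for-sample with the 405-nm control
#' channel; the control carries the bleach and motion but no transients.
#'
#' @param bleach_a1,bleach_tau1,bleach_a2,bleach_tau2,bleach_c bleaching
#'   baseline parameters `a1 exp(-t/tau1) + a2 exp(-t/tau2) + c`
#'   (`tau1 > tau2 > 0`, seconds).
#' @param kernel_amp,kernel_rise_s,kernel_decay_s transient kernel: peak
#'   amplitude (fraction of tonic) and rise/decay time constants.
#' @param event_times_s calcium-transient onset times, seconds.
#' @param tonic tonic fluorescence level (a.u.).
#' @param noise_sd additive noise SD (a.u.).
#' @param motion_times_s,motion_gain movement-artifact bump times and
#'   amplitude (shared with the control channel).
#' @param control_scale multiplicative scale of the control channel's
#'   bleach/tonic relative to the signal channel.
#' @param seed integer RNG seed.
#' @return list of class `"photometry_truth"`.
#' @export
photometry_truth <- function(bleach_a1 = 30, bleach_tau1 = 1800,
                             bleach_a2 = 10, bleach_tau2 = 120,
                             bleach_c = 60, kernel_amp = 0.15,
                             kernel_rise_s = 1, kernel_decay_s = 4,
                             event_times_s = numeric(), tonic = 1,
                             noise_sd = 0.2, motion_times_s = numeric(),
                             motion_gain = 0, control_scale = 0.6,
                             seed = 1L) {
  if (bleach_tau1 <= 0 || bleach_tau2 <= 0)
    stop("bleach decay constants must be positive")
  if (kernel_decay_s <= 0 || kernel_rise_s <= 0)
    stop("kernel time constants must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(bleach_a1 = bleach_a1, bleach_tau1 = bleach_tau1,
                 bleach_a2 = bleach_a2, bleach_tau2 = bleach_tau2,
                 bleach_c = bleach_c, kernel_amp = kernel_amp,
                 kernel_rise_s = kernel_rise_s,
                 kernel_decay_s = kernel_decay_s,
                 event_times_s = event_times_s, tonic = tonic,
                 noise_sd = noise_sd, motion_times_s = motion_times_s,
                 motion_gain = motion_gain, control_scale = control_scale,
                 seed = as.integer(seed)),
            class = "photometry_truth")
}

# difference-of-exponentials kernel, peak-normalized to 1
doe_kernel <- function(t, rise, decay) {
  k <- exp(-t / decay) - exp(-t / rise)
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  pk <- exp(-tp / decay) - exp(-tp / rise)
  ifelse(t >= 0, k / pk, 0)
}

bleach_curve <- function(truth, t_s) {
  truth$bleach_a1 * exp(-t_s / truth$bleach_tau1) +
    truth$bleach_a2 * exp(-t_s / truth$bleach_tau2) + truth$bleach_c
}

#' Simulate a fiber-photometry session
#'
#' @param truth a [photometry_truth()].
#' @param duration_s recording length, seconds.
#' @param fs sampling rate, Hz (raw photometry is later downsampled to 1 Hz
#'   by [downsample()]).
#' @return a [photometry_session()] with signal, control, and the truth's
#'   transient times listed as events of kind `"transient"`.
#' @export
simulate_photometry <- function(truth, duration_s = 1800, fs = 10) {
  stopifnot(inherits(truth, "photometry_truth"))
  if (duration_s <= 0) stop("'duration_s' must be positive")
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  trans <- numeric(length(t))
  for (te in truth$event_times_s)
    trans <- trans + truth$kernel_amp *
      doe_kernel(t - te, truth$kernel_rise_s, truth$kernel_decay_s)
  motion <- numeric(length(t))
  for (tm in truth$motion_times_s)
    motion <- motion + truth$motion_gain * exp(-(t - tm)^2 / (2 * 0.5^2))
  bl <- bleach_curve(truth, t)
  with_seed(truth$seed, {
    nz1 <- if (truth$noise_sd > 0) stats::rnorm(length(t), 0, truth$noise_sd) else 0
    nz2 <- if (truth$noise_sd > 0) stats::rnorm(length(t), 0, truth$noise_sd) else 0
  })
  signal <- bl * (truth$tonic + trans) + nz1 + motion
  control <- truth$control_scale * bl * truth$tonic + nz2 + motion
  ev <- if (length(truth$event_times_s))
    data.frame(t_s = truth$event_times_s, kind = "transient") else
    data.frame(t_s = numeric(), kind = character())
  photometry_session(signal = regts(signal, 1 / fs, units = "a.u."),
                     control = regts(control, 1 / fs, units = "a.u."),
                     events = ev)
}

#' Ground truth for a synthetic circuit-mapping recording
#'
#' Per light pulse, an evoked IPSC occurs with probability `p_evoked` at a
#' jittered latency; spontaneous events arrive as a Poisson process
#' throughout the session. Amplitudes are Gaussian.
#'
#' @param connected ground-truth connection flag (metadata; the generated
#'   statistics derive from `p_evoked`).
#' @param p_evoked per-pulse evoked-response probability in `[0, 1]`.
#' @param latency_mean_ms,latency_jitter_ms evoked latency mean and SD, ms.
#' @param amp_mean_pa,amp_sd_pa evoked amplitude distribution, pA.
#' @param baseline_rate_hz spontaneous IPSC rate, Hz.
#' @param n_trials number of light pulses (the recording convention is a
#'   minimum of 30).
#' @param protocol a [stim_protocol()]; default single 10-ms pulses at
#'   0.1 Hz for `n_trials` trials.
#' @param seed integer RNG seed.
#' @return list of class `"cracm_truth"`.
#' @export
cracm_truth <- function(connected = TRUE, p_evoked = 0.95,
                        latency_mean_ms = 10, latency_jitter_ms = 1,
                        amp_mean_pa = 107.2, amp_sd_pa = 25,
                        baseline_rate_hz = 0.5, n_trials = 30,
                        protocol = NULL, seed = 1L) {
  if (p_evoked < 0 || p_evoked > 1) stop("'p_evoked' must be in [0, 1]")
  if (latency_mean_ms <= 0) stop("'latency_mean_ms' must be positive")
  if (baseline_rate_hz < 0) stop("rates must be >= 0")
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (is.null(protocol))
    protocol <- stim_protocol("single", n_trials = n_trials)
  structure(list(connected = isTRUE(connected), p_evoked = p_evoked,
                 latency_mean_ms = latency_mean_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 amp_mean_pa = amp_mean_pa, amp_sd_pa = amp_sd_pa,
                 baseline_rate_hz = baseline_rate_hz,
                 n_trials = as.integer(n_trials), protocol = protocol,
                 seed = as.integer(seed)),
            class = "cracm_truth")
}

#' Simulate a circuit-mapping stimulation session
#'
#' @param truth a [cracm_truth()].
#' @param render if `TRUE`, also render the summed IPSC current trace
#'   (difference-of-exponentials waveforms, rise/decay per
#'   `kinetics`) for event-detector testing.
#' @param fs sampling rate of the rendered trace, Hz.
#' @param kinetics IPSC waveform rise/decay time constants in ms.
#' @return a [stim_session()].
#' @export
simulate_cracm <- function(truth, render = FALSE, fs = 5000,
                           kinetics = c(rise_ms = 1, decay_ms = 10)) {
  stopifnot(inherits(truth, "cracm_truth"))
  onsets <- truth$protocol$pulse_onsets_s
  total_s <- max(onsets) + truth$protocol$inter_trial_s
  with_seed(truth$seed, {
    n_base <- stats::rpois(1, truth$baseline_rate_hz * total_s)
    t_base <- sort(stats::runif(n_base, 0, total_s))
    a_base <- stats::rnorm(n_base, truth$amp_mean_pa, truth$amp_sd_pa)
    hit <- stats::runif(length(onsets)) < truth$p_evoked
    lat <- pmax(0.1, stats::rnorm(sum(hit), truth$latency_mean_ms,
                                  truth$latency_jitter_ms)) / 1000
    t_ev <- onsets[hit] + lat
    a_ev <- stats::rnorm(sum(hit), truth$amp_mean_pa, truth$amp_sd_pa)
  })
  ev <- data.frame(t_s = c(t_base, t_ev),
                   amplitude_pA = pmax(5, c(a_base, a_ev)))
  ev <- ev[order(ev$t_s), , drop = FALSE]
  rownames(ev) <- NULL
  trace <- NULL
  if (render) {
    t <- (seq_len(round(total_s * fs)) - 1) / fs
    i_pa <- numeric(length(t))
    for (k in seq_len(nrow(ev))) {
      idx <- which(t >= ev$t_s[k] & t <= ev$t_s[k] + 10 * kinetics[["decay_ms"]] / 1000)
      i_pa[idx] <- i_pa[idx] + ev$amplitude_pA[k] *
        doe_kernel(t[idx] - ev$t_s[k], kinetics[["rise_ms"]] / 1000,
                   kinetics[["decay_ms"]] / 1000)
    }
    trace <- regts(i_pa, 1 / fs, units = "pA")
  }
  stim_session(protocol = truth$protocol, events = ev, trace = trace,
               holding_mV = 0)
}
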