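#' Optogenetic stimulation protocol
#'
#' @param mode `"single"` (repeated single pulses, default 10-ms pulses at
#'   0.1 Hz) or `"train"` (10-s trains at 10 Hz of 10-ms pulses).
#' @param n_trials number of trials (single pulses or trains).
#' @param pulse_dur_ms light-pulse duration, ms.
#' @param inter_trial_s interval between trial onsets, seconds.
#' @param train_freq_hz,train_dur_s train parameters (train mode only).
#' @param pulse_onsets_s explicit pulse onsets (override), seconds.
#' @return object of class `"stim_protocol"` with strictly increasing
#'   `pulse_onsets_s`.
#' @export
stim_protocol <- function(mode = c("single", "train"), n_trials = 30,
                          pulse_dur_ms = 10, inter_trial_s = 10,
                          train_freq_hz = 10, train_dur_s = 10,
                          pulse_onsets_s = NULL) {
  mode <- match.arg(mode)
  if (is.null(pulse_onsets_s)) {
    trial_starts <- (seq_len(n_trials) - 1) * inter_trial_s + 1
    pulse_onsets_s <- if (mode == "single") trial_starts
    else as.vector(outer(seq(0, train_dur_s - 1 / train_freq_hz,
                             by = 1 / train_freq_hz), trial_starts, `+`))
  }
  if (is.unsorted(pulse_onsets_s, strictly = TRUE))
    stop("pulse onsets must be strictly increasing")
  structure(list(mode = mode, pulse_onsets_s = pulse_onsets_s,
                 pulse_dur_ms = pulse_dur_ms,
                 train_freq_hz = if (mode == "train") train_freq_hz else NA,
                 inter_trial_s = inter_trial_s),
            class = "stim_protocol")
}

#' Stimulation session: protocol plus detected or simulated events
#'
#' @param protocol a [stim_protocol()].
#' @param events data.frame `t_s`, `amplitude_pA` of synaptic events.
#' @param trace optional rendered current trace as a [regts()] (pA,
#'   outward-positive at 0 mV holding).
#' @param holding_mV holding potential, mV.
#' @return object of class `"stim_session"`.
#' @export
stim_session <- function(protocol, events, trace = NULL, holding_mV = 0) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (length(protocol$pulse_onsets_s) < 1) stop("at least one trial required")
  structure(list(protocol = protocol, events = events, trace = trace,
                 holding_mV = holding_mV),
            class = "stim_session")
}

#' @export
print.stim_session <- function(x, ...) {
  cat(sprintf("Stim session: %s mode, %d pulses, %d events, trace %s\n",
              x$protocol$mode, length(x$protocol$pulse_onsets_s),
              nrow(x$events), if (is.null(x$trace)) "absent" else "present"))
  invisible(x)
}

#' Detect synaptic events on a rendered current trace
#'
#' Threshold/extremum detector for outward (positive) current deflections:
#' local maxima of the deflection from the trace median exceeding
#' `threshold_pA`, accepted greedily in time order with a refractory
#' separation of `min_interval_ms` (closer peaks merge into one event).
#' The onset is the first threshold crossing preceding each accepted peak.
#'
#' @param trace a [regts()] current trace in pA.
#' @param threshold_pA detection threshold above the local baseline.
#' @param min_interval_ms minimum separation between events, ms.
#' @return data.frame: `t_onset_s`, `t_peak_s`, `amplitude_pA` (empty for
#'   a flat trace).
#' @export
detect_events <- function(trace, threshold_pA = 20, min_interval_ms = 20) {
  x <- trace$values - stats::median(trace$values)
  n <- length(x)
  empty <- data.frame(t_onset_s = numeric(), t_peak_s = numeric(),
                      amplitude_pA = numeric())
  above <- x > threshold_pA
  if (!any(above)) return(empty)
  is_pk <- above & x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf)
  pk <- which(is_pk)
  if (!length(pk)) return(empty)
  min_gap <- min_interval_ms / 1000
  t <- time_s(trace)
  keep <- pk[1]; last_t <- t[pk[1]]
  for (i in pk[-1]) {
    if (t[i] - last_t >= min_gap) { keep <- c(keep, i); last_t <- t[i] }
  }
  onset <- vapply(keep, function(i) {
    j <- i
    while (j > 1 && above[j - 1]) j <- j - 1
    t[j]
  }, 0)
  data.frame(t_onset_s = onset, t_peak_s = t[keep], amplitude_pA = x[keep])
}

# events (or detected events) of a session as times + amplitudes
session_events <- function(session) {
  ev <- session$events
  if (!is.null(ev) && nrow(ev)) {
    names(ev)[1] <- "t_s"
    return(ev)
  }
  if (!is.null(session$trace)) {
    d <- detect_events(session$trace)
    return(data.frame(t_s = d$t_onset_s, amplitude_pA = d$amplitude_pA))
  }
  data.frame(t_s = numeric(), amplitude_pA = numeric())
}

# indices of events in (onset, onset + w] per pulse; w in seconds
first_event_in_window <- function(ev_t, onset, w)
  which(ev_t > onset & ev_t <= onset + w)[1L]

#' Evoked-response probability
#'
#' Percentage of light pulses followed by at least one synaptic event in
#' the half-open window `(onset, onset + window_ms]`; an event exactly at
#' the onset counts as baseline, not response.
#'
#' @param session a [stim_session()].
#' @param window_ms response window after pulse onset, ms (default 50).
#' @return probability in percent.
#' @export
response_probability <- function(session, window_ms = 50) {
  ev <- session_events(session)$t_s
  on <- session$protocol$pulse_onsets_s
  w <- window_ms / 1000
  100 * mean(vapply(on, function(o) any(ev > o & ev <= o + w), TRUE))
}

#' Baseline event probability in matched pre-pulse windows
#'
#' The comparator statistic for the connectivity criterion: the same
#' probability computed in a matched-duration window ending at each pulse
#' onset, `(onset - window_ms, onset]`. Pulses must be separated by more
#' than twice the window so baseline and response windows cannot overlap.
#'
#' @inheritParams response_probability
#' @return probability in percent.
#' @export
baseline_probability <- function(session, window_ms = 50) {
  on <- session$protocol$pulse_onsets_s
  w <- window_ms / 1000
  if (length(on) > 1 && min(diff(on)) <= 2 * w)
    stop("pulses too close: baseline windows would overlap response windows")
  if (on[1] < w) stop("first pulse too early for a matched baseline window")
  ev <- session_events(session)$t_s
  100 * mean(vapply(on, function(o) any(ev > o - w & ev <= o), TRUE))
}

#' Connected-cell criterion
#'
#' A recorded cell is classified as synaptically connected when its evoked
#' IPSC probability in the first 50 ms after the light pulse is strictly
#' greater than 50%.
#'
#' @param response_prob response probability in percent, `[0, 100]`.
#' @param criterion_pct threshold in percent (default 50, strict).
#' @return logical flag.
#' @export
classify_connected <- function(response_prob, criterion_pct = 50) {
  if (any(response_prob < 0 | response_prob > 100))
    stop("probabilities must be in [0, 100]")
  response_prob > criterion_pct
}

#' Evoked IPSC latency per responsive pulse
#'
#' Latency is the time from pulse onset to the 5%-of-peak rise point of the
#' first IPSC in the response window. With a rendered trace the rise point
#' is located on the waveform (first sample at or above 5% of the event
#' peak deflection, walking back from the peak); with an event list only,
#' the event onset time is used and the result is flagged `onset_based`.
#'
#' @param session a [stim_session()].
#' @param window_ms response window, ms.
#' @param threshold_pA,min_interval_ms detector settings for trace-based
#'   latency.
#' @return list: `latency_ms` (per responsive pulse), `mean_ms`, `sem_ms`,
#'   `onset_based`, `n_responsive`. Latencies are undefined (empty, with a
#'   warning) when no pulse is responsive.
#' @export
evoked_latency <- function(session, window_ms = 50, threshold_pA = 20,
                           min_interval_ms = 5) {
  on <- session$protocol$pulse_onsets_s
  w <- window_ms / 1000
  use_trace <- !is.null(session$trace)
  if (use_trace) {
    det <- detect_events(session$trace, threshold_pA, min_interval_ms)
    t <- time_s(session$trace)
    x <- session$trace$values - stats::median(session$trace$values)
    lat <- vapply(on, function(o) {
      k <- which(det$t_onset_s > o & det$t_onset_s <= o + w)[1L]
      if (is.na(k)) return(NA_real_)
      ip <- which.min(abs(t - det$t_peak_s[k]))
      thr <- 0.05 * x[ip]
      j <- ip
      while (j > 1 && x[j - 1] >= thr && t[j - 1] > o) j <- j - 1
      (t[j] - o) * 1000
    }, 0)
  } else {
    ev <- session_events(session)$t_s
    lat <- vapply(on, function(o) {
      k <- first_event_in_window(ev, o, w)
      if (is.na(k)) NA_real_ else (ev[k] - o) * 1000
    }, 0)
  }
  lat <- lat[!is.na(lat)]
  if (!length(lat)) warning("no responsive pulses: latency undefined")
  list(latency_ms = lat, mean_ms = if (length(lat)) mean(lat) else NA_real_,
       sem_ms = if (length(lat) > 1) stats::sd(lat) / sqrt(length(lat)) else NA_real_,
       onset_based = !use_trace, n_responsive = length(lat))
}

#' Evoked IPSC amplitude summary
#'
#' Mean and s.e.m. of the first-event peak amplitude over responsive
#' pulses.
#'
#' @inheritParams response_probability
#' @return list: `amplitudes_pA`, `mean_pA`, `sem_pA` (`NA` with a single
#'   responsive pulse), `n_responsive`.
#' @export
amplitude_summary <- function(session, window_ms = 50) {
  ev <- session_events(session)
  on <- session$protocol$pulse_onsets_s
  w <- window_ms / 1000
  amp <- vapply(on, function(o) {
    k <- first_event_in_window(ev$t_s, o, w)
    if (is.na(k)) NA_real_ else ev$amplitude_pA[k]
  }, 0)
  amp <- amp[!is.na(amp)]
  if (!length(amp)) stop("no responsive pulses")
  list(amplitudes_pA = amp, mean_pA = mean(amp),
       sem_pA = if (length(amp) > 1) stats::sd(amp) / sqrt(length(amp)) else NA_real_,
       n_responsive = length(amp))
}

#' Full connectivity summary for a stimulation session
#'
#' Computes the response and baseline probabilities, the connected-cell
#' classification, and latency and amplitude summaries in one call.
#'
#' @inheritParams response_probability
#' @param criterion_pct connectivity criterion in percent (default 50).
#' @return object of class `"connectivity_result"`.
#' @export
cracm_connectivity <- function(session, window_ms = 50, criterion_pct = 50) {
  rp <- response_probability(session, window_ms)
  bp <- tryCatch(baseline_probability(session, window_ms),
                 error = function(e) NA_real_)
  conn <- classify_connected(rp, criterion_pct)
  lat <- if (rp > 0) evoked_latency(session, window_ms) else
    list(mean_ms = NA_real_, sem_ms = NA_real_, n_responsive = 0L,
         onset_based = TRUE)
  amp <- if (rp > 0) amplitude_summary(session, window_ms) else
    list(mean_pA = NA_real_, sem_pA = NA_real_, n_responsive = 0L)
  structure(list(response_prob = rp, baseline_prob = bp, connected = conn,
                 latency = lat, amplitude = amp,
                 n_trials = length(session$protocol$pulse_onsets_s),
                 window_ms = window_ms, criterion_pct = criterion_pct),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("Connectivity over %d pulses (%g-ms window):\n", x$n_trials,
              x$window_ms))
  cat(sprintf("  response probability %.2f%%  (baseline %s%%)  -> %s\n",
              x$response_prob,
              if (is.na(x$baseline_prob)) "NA" else sprintf("%.2f", x$baseline_prob),
              if (x$connected) "CONNECTED" else "not connected"))
  if (!is.na(x$latency$mean_ms))
    cat(sprintf("  latency %.2f +/- %.2f ms%s, amplitude %.1f +/- %.1f pA (n = %d)\n",
                x$latency$mean_ms, x$latency$sem_ms %||% NA,
                if (x$latency$onset_based) " (onset-based)" else "",
                x$amplitude$mean_pA, x$amplitude$sem_pA %||% NA,
                x$amplitude$n_responsive))
  invisible(x)
}
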