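#' Fiber-photometry session container
#'
#' @param signal calcium-dependent channel as a [regts()].
#' @param control optional 405-nm (calcium-independent) control channel
#'   sharing the signal's sampling rate.
#' @param events data.frame `t_s`, `kind` (e.g. `light_pulse_on`,
#'   `light_pulse_off`, `state_transition`, `transient`); times must fall
#'   within the recording span.
#' @param hypnogram optional [hypnogram()] covering the recording.
#' @return object of class `"photometry_session"`.
#' @export
photometry_session <- function(signal, control = NULL,
                               events = data.frame(t_s = numeric(),
                                                   kind = character()),
                               hypnogram = NULL) {
  stopifnot(inherits(signal, "regts"))
  if (!is.null(control)) {
    stopifnot(inherits(control, "regts"))
    if (abs(control$dt_s - signal$dt_s) > 1e-12)
      stop("signal and control must share sampling rate")
  }
  span <- length(signal$values) * signal$dt_s
  if (nrow(events) && any(events$t_s < 0 | events$t_s > span))
    stop("event times outside the recording span")
  structure(list(signal = signal, control = control, events = events,
                 hypnogram = hypnogram),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  span <- length(x$signal$values) * x$signal$dt_s
  cat(sprintf("Photometry session: %.1f s @ %g Hz, control %s, %d events\n",
              span, 1 / x$signal$dt_s,
              if (is.null(x$control)) "absent" else "present",
              nrow(x$events)))
  invisible(x)
}

#' Downsample a trace by non-overlapping window means
#'
#' @param ts a [regts()] (or a [photometry_session()], in which case both
#'   channels are downsampled).
#' @param target_hz target rate; the current rate must be an integer
#'   multiple of it (default 1 Hz, the rate used for all downstream
#'   processing).
#' @return downsampled object of the same class.
#' @export
downsample <- function(ts, target_hz = 1) {
  if (inherits(ts, "photometry_session")) {
    ts$signal <- downsample(ts$signal, target_hz)
    if (!is.null(ts$control)) ts$control <- downsample(ts$control, target_hz)
    return(ts)
  }
  fs <- fs_hz(ts)
  if (fs < target_hz) stop("sampling rate below the target rate")
  k <- fs / target_hz
  if (abs(k - round(k)) > 1e-9)
    stop("sampling rate must be an integer multiple of the target rate")
  k <- as.integer(round(k))
  n_out <- length(ts$values) %/% k
  out <- colMeans(matrix(ts$values[seq_len(n_out * k)], nrow = k))
  regts(out, 1 / target_hz, ts$start, ts$units)
}

#' Fit the photobleaching baseline F0
#'
#' Fits `F0(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + c` (slow and fast
#' bleaching components plus an offset, `tau1 > tau2 > 0`) by
#' Levenberg-Marquardt nonlinear least squares with multi-start
#' initialization over log-spaced time constants. If no two-term start
#' converges the fit falls back to a single exponential (with a warning),
#' and a near-constant trace returns the degenerate `a1 = a2 = 0`,
#' `F0 = c` solution directly.
#'
#' @param ts a [regts()] fluorescence trace spanning at least 60 s.
#' @return list of class `"bleach_fit"`: `params` (a1, tau1, a2, tau2, c),
#'   `f0` (fitted baseline, same length as the trace), `form`
#'   (`"biexponential"`, `"exponential"` or `"constant"`), `rss`.
#' @export
fit_bleach_baseline <- function(ts) {
  t <- time_s(ts); y <- ts$values
  span <- max(t)
  if (span < 60) stop("trace must span at least 60 s")
  const_fit <- function() list(
    params = c(a1 = 0, tau1 = span, a2 = 0, tau2 = span / 10, c = mean(y)),
    f0 = rep(mean(y), length(y)), form = "constant",
    rss = sum((y - mean(y))^2))
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) return(const_fit())
  drop0 <- y[1] - y[length(y)]
  best <- NULL
  for (tau1 in span * c(1, 0.3)) for (tau2 in span * c(0.1, 0.02)) {
    st <- list(a1 = drop0 * 0.7, tau1 = tau1, a2 = drop0 * 0.3, tau2 = tau2,
               c = min(y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c,
                        start = st,
                        lower = c(-Inf, 1e-6, -Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (!is.null(best)) {
    p <- as.list(stats::coef(best$fit))
    if (p$tau1 < p$tau2) p <- list(a1 = p$a2, tau1 = p$tau2, a2 = p$a1,
                                   tau2 = p$tau1, c = p$c)
    return(list(params = c(a1 = p$a1, tau1 = p$tau1, a2 = p$a2,
                           tau2 = p$tau2, c = p$c),
                f0 = p$a1 * exp(-t / p$tau1) + p$a2 * exp(-t / p$tau2) + p$c,
                form = "biexponential", rss = best$rss))
  }
  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-t / tau1) + c,
                      start = list(a1 = drop0, tau1 = span / 3, c = min(y)),
                      lower = c(-Inf, 1e-6, -Inf)),
    error = function(e) NULL)
  if (!is.null(fit1)) {
    warning("two-term exponential did not converge; single-exponential fallback")
    p <- as.list(stats::coef(fit1))
    return(list(params = c(a1 = p$a1, tau1 = p$tau1, a2 = 0,
                           tau2 = p$tau1 / 10, c = p$c),
                f0 = p$a1 * exp(-t / p$tau1) + p$c,
                form = "exponential", rss = sum(stats::resid(fit1)^2)))
  }
  stop("bleach baseline fit failed to converge in both forms")
}

#' Baseline-relative fluorescence dF/F
#'
#' `(F_t - F0_t) / F0_t` elementwise against a fitted bleaching baseline,
#' which removes the bleaching trend and expresses fluorescence as a
#' fraction of baseline.
#'
#' @param ts a [regts()] fluorescence trace.
#' @param f0 baseline: a `"bleach_fit"` from [fit_bleach_baseline()] or a
#'   numeric vector of the trace's length; must be positive everywhere.
#' @return a [regts()] of dimensionless dF/F values.
#' @export
dff <- function(ts, f0) {
  if (is.list(f0) && !is.null(f0$f0)) f0 <- f0$f0
  if (length(f0) != length(ts$values)) stop("F0 length mismatch")
  if (any(f0 <= 0)) stop("F0 must be positive everywhere")
  regts((ts$values - f0) / f0, ts$dt_s, ts$start, "dF/F")
}

#' Z-score a dF/F trace
#'
#' Standardizes to mean 0 and SD 1 over the recording segment, the
#' normalization used to compare fluorescence levels between subjects.
#'
#' @param ts a [regts()] (typically a dF/F trace).
#' @return a [regts()] in z-units.
#' @export
standardize <- function(ts) {
  s <- stats::sd(ts$values)
  if (s == 0) stop("zero-variance trace cannot be standardized")
  regts((ts$values - mean(ts$values)) / s, ts$dt_s, ts$start, "z")
}

#' Zero a trace at a transition by the preceding median
#'
#' Extracts the `[t0 - pre_s, t0 + post_s)` window and subtracts the median
#' of the `pre_s` seconds preceding the transition, so the pre-window
#' median of the returned trace is exactly zero. Applying the operation
#' twice changes nothing.
#'
#' @param ts a [regts()].
#' @param t0 transition time, seconds from trace start.
#' @param pre_s,post_s window half-widths, seconds (default 60 each).
#' @return the zeroed window as a [regts()].
#' @export
zero_at_transition <- function(ts, t0, pre_s = 60, post_s = 60) {
  t <- time_s(ts)
  span <- length(ts$values) * ts$dt_s
  if (t0 - pre_s < 0 || t0 + post_s > span)
    stop("transition window extends beyond the recording")
  pre <- ts$values[t >= t0 - pre_s & t < t0]
  win <- which(t >= t0 - pre_s & t < t0 + post_s)
  regts(ts$values[win] - stats::median(pre), ts$dt_s,
        ts$start + (t0 - pre_s), ts$units)
}

#' Pre/post event response with a paired test across sessions
#'
#' For each session, averages the trace over the `window_s` seconds
#' preceding and following its event time; across sessions the pre and
#' post means are compared with a two-tailed paired t-test. With fewer
#' than two sessions, or zero variance of the paired differences, only the
#' means are returned and the test is flagged unavailable.
#'
#' @param traces list of [regts()] traces (one per session/subject).
#' @param t0 event time(s), seconds; recycled across sessions.
#' @param window_s averaging window, seconds (default 10).
#' @return list: `per_session` data.frame (`pre_mean`, `post_mean`,
#'   `diff`), `t`, `df`, `p_value` (NA when flagged), `test_available`.
#' @export
pre_post_response <- function(traces, t0, window_s = 10) {
  if (inherits(traces, "regts")) traces <- list(traces)
  t0 <- rep_len(t0, length(traces))
  res <- t(mapply(function(ts, e) {
    t <- time_s(ts)
    span <- length(ts$values) * ts$dt_s
    if (e - window_s < 0 || e + window_s > span)
      stop("pre/post window outside the recording span")
    c(pre_mean = mean(ts$values[t >= e - window_s & t < e]),
      post_mean = mean(ts$values[t >= e & t < e + window_s]))
  }, traces, t0))
  per <- data.frame(res)
  per$diff <- per$post_mean - per$pre_mean
  out <- list(per_session = per, t = NA_real_, df = NA_real_,
              p_value = NA_real_, test_available = FALSE)
  if (nrow(per) >= 2 && stats::sd(per$diff) > 0) {
    tt <- stats::t.test(per$post_mean, per$pre_mean, paired = TRUE)
    out$t <- unname(tt$statistic); out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value; out$test_available <- TRUE
  } else if (nrow(per) >= 2) {
    warning("zero-variance paired differences; t-test unavailable")
  }
  out
}

#' Event-aligned trace matrix with mean and s.e.m.
#'
#' @param ts a [regts()].
#' @param event_times_s event times, seconds from trace start; all windows
#'   must lie within the recording.
#' @param pre_s,post_s window extent around each event, seconds.
#' @return list: `matrix` (rows = events, columns = time bins), `time_s`
#'   (relative to event), `mean`, `sem`, `n_events`. Zero events return an
#'   empty matrix with a warning.
#' @export
align_events <- function(ts, event_times_s, pre_s, post_s) {
  n_bins <- as.integer(round((pre_s + post_s) / ts$dt_s))
  rel_t <- -pre_s + (seq_len(n_bins) - 1) * ts$dt_s
  if (length(event_times_s) == 0L) {
    warning("no events to align")
    return(list(matrix = matrix(numeric(), 0, n_bins), time_s = rel_t,
                mean = rep(NA_real_, n_bins), sem = rep(NA_real_, n_bins),
                n_events = 0L))
  }
  span <- length(ts$values) * ts$dt_s
  if (any(event_times_s - pre_s < 0 | event_times_s + post_s > span))
    stop("alignment window outside the recording span")
  m <- t(vapply(event_times_s, function(e) {
    i0 <- as.integer(round((e - pre_s) / ts$dt_s))
    ts$values[i0 + seq_len(n_bins)]
  }, numeric(n_bins)))
  list(matrix = m, time_s = rel_t, mean = colMeans(m),
       sem = apply(m, 2, stats::sd) / sqrt(nrow(m)), n_events = nrow(m))
}

#' State-resolved mean activity
#'
#' Time-weighted mean of a (z-scored) trace over epochs of each vigilance
#' state, optionally split by condition windows (e.g. before / during /
#' after a light pulse).
#'
#' @param ts a [regts()] (typically 1-Hz z-trace).
#' @param hyp a [hypnogram()] covering the trace span.
#' @param windows optional named list of `c(from_s, to_s)` condition
#'   windows (half-open, seconds from trace start); default one window over
#'   the whole trace.
#' @return data.frame: `window`, `state`, `mean_z`, `seconds` (`NA` mean
#'   where the state has no epochs in the window).
#' @export
state_resolved_activity <- function(ts, hyp, windows = NULL) {
  t <- time_s(ts)
  span <- length(ts$values) * ts$dt_s
  if (length(hyp$labels) * hyp$epoch_s < span - 1e-9)
    stop("hypnogram does not cover the trace span")
  lab <- hyp$labels[pmin(floor(t / hyp$epoch_s) + 1, length(hyp$labels))]
  if (is.null(windows)) windows <- list(all = c(0, span))
  states <- c("Wake", "NREM", "REM")
  out <- expand.grid(window = names(windows), state = states,
                     stringsAsFactors = FALSE)
  out$mean_z <- NA_real_; out$seconds <- 0
  for (i in seq_len(nrow(out))) {
    w <- windows[[out$window[i]]]
    sel <- t >= w[1] & t < w[2] & lab == out$state[i]
    out$seconds[i] <- sum(sel) * ts$dt_s
    if (any(sel)) out$mean_z[i] <- mean(ts$values[sel])
  }
  out
}

#' Movement-artifact screen against the control channel
#'
#' Recordings in which the calcium-independent control channel moves in
#' parallel with the signal are assumed contaminated by movement and
#' dropped: the trace is split into non-overlapping windows, each window's
#' linearly detrended signal/control correlation is computed, and the
#' session is rejected when more than half the windows correlate above
#' `r_threshold`.
#'
#' @param signal,control [regts()] channels at the same rate.
#' @param window_s correlation window, seconds.
#' @param r_threshold correlation threshold (default 0.7).
#' @return list: `keep` (logical; `TRUE` when `control` is `NULL`, with a
#'   warning), `fraction_correlated`, `window_r`.
#' @export
motion_artifact_check <- function(signal, control, window_s = 30,
                                  r_threshold = 0.7) {
  if (is.null(control)) {
    warning("no control channel: motion-artifact check skipped")
    return(list(keep = TRUE, fraction_correlated = NA_real_,
                window_r = numeric()))
  }
  k <- as.integer(round(window_s / signal$dt_s))
  n_win <- length(signal$values) %/% k
  if (n_win < 1) stop("trace shorter than one correlation window")
  detrend <- function(x) stats::resid(stats::lm(x ~ seq_along(x)))
  r <- vapply(seq_len(n_win), function(i) {
    idx <- ((i - 1) * k + 1):(i * k)
    s <- detrend(signal$values[idx]); c0 <- detrend(control$values[idx])
    if (stats::sd(s) == 0 || stats::sd(c0) == 0) 0 else stats::cor(s, c0)
  }, 0)
  frac <- mean(r > r_threshold)
  list(keep = frac <= 0.5, fraction_correlated = frac, window_r = r)
}
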