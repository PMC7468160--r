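#' Hypnogram: per-epoch vigilance-state labels
#'
#' @param labels character vector over `Wake`, `NREM`, `REM`, `Artifact`.
#' @param epoch_s epoch length in seconds (10 s for scoring, 5 s for
#'   spectral analysis).
#' @param start timestamp of the first epoch.
#' @return object of class `"hypnogram"`.
#' @export
hypnogram <- function(labels, epoch_s = 10,
                      start = "2024-01-01 07:00:00") {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("'labels' must be non-empty")
  bad <- setdiff(unique(labels), c("Wake", "NREM", "REM", "Artifact"))
  if (length(bad)) stop("unknown vigilance labels: ", paste(bad, collapse = ", "))
  if (epoch_s <= 0) stop("'epoch_s' must be positive")
  if (!inherits(start, "POSIXct")) start <- as.POSIXct(start, tz = "UTC")
  structure(list(labels = labels, epoch_s = epoch_s, start = start),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("Hypnogram: %d epochs x %g s (%.2f h)\n", n, x$epoch_s,
              n * x$epoch_s / 3600))
  print(round(100 * table(factor(x$labels,
      c("Wake", "NREM", "REM", "Artifact"))) / n, 1))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

# continuous ZT hours of each epoch start
hyp_zt <- function(hyp, schedule) {
  lt <- as.POSIXlt(hyp$start)
  clock0 <- lt$hour + lt$min / 60 + lt$sec / 3600
  (clock0 - schedule$lights_on) %% 24 +
    (seq_along(hyp$labels) - 1) * hyp$epoch_s / 3600
}

#' Canonical EEG frequency bands
#'
#' The six bands partition 0.5-120 Hz without overlap: delta 0.5-5, theta
#' 5-9, sigma 9-15, beta 15-30, low gamma 30-60, high gamma 60-120 Hz
#' (half-open on the right except the last, which includes 120 Hz).
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "sigma", "beta",
                      "low_gamma", "high_gamma"),
             lo = c(0.5, 5, 9, 15, 30, 60),
             hi = c(5, 9, 15, 30, 60, 120))
}

# Hann-tapered one-sided power spectrum of one epoch; returns freq + power
epoch_spectrum <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  X <- stats::fft((x - mean(x)) * w)
  half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(half)])^2 / sum(w^2)
  p[-c(1L, if (n %% 2 == 0) half)] <- 2 * p[-c(1L, if (n %% 2 == 0) half)]
  list(freq = (seq_len(half) - 1) * fs / n, power = p)
}

#' Per-epoch scoring features from EEG and EMG
#'
#' Computes, for consecutive epochs, the EMG root-mean-square over raw
#' samples and the EEG delta (0.5-5 Hz) and theta (5-9 Hz) power by
#' Hann-tapered periodogram integration, plus the theta:delta ratio used to
#' separate REM from NREM.
#'
#' @param eeg,emg [regts()] signals sharing sampling rate and span;
#'   `fs >= 100` Hz required.
#' @param epoch_s epoch length in seconds (default 10).
#' @return data.frame of class `"epoch_features"`: `epoch`, `emg_rms`,
#'   `delta_power`, `theta_power`, `theta_delta_ratio` (`NA` where delta
#'   power is zero).
#' @export
compute_epoch_features <- function(eeg, emg, epoch_s = 10) {
  fs <- fs_hz(eeg)
  if (abs(fs - fs_hz(emg)) > 1e-9) stop("EEG and EMG must share sampling rate")
  if (length(eeg$values) != length(emg$values))
    stop("EEG and EMG must share span")
  if (fs < 100) stop("fs must be >= 100 Hz")
  spe <- as.integer(round(epoch_s * fs))
  n_ep <- length(eeg$values) %/% spe
  if (n_ep == 0L) stop("signals shorter than one epoch")
  out <- data.frame(epoch = seq_len(n_ep), emg_rms = NA_real_,
                    delta_power = NA_real_, theta_power = NA_real_)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1) * spe + 1):(i * spe)
    out$emg_rms[i] <- sqrt(mean(emg$values[idx]^2))
    sp <- epoch_spectrum(eeg$values[idx], fs)
    out$delta_power[i] <- sum(sp$power[sp$freq >= 0.5 & sp$freq < 5])
    out$theta_power[i] <- sum(sp$power[sp$freq >= 5 & sp$freq < 9])
  }
  out$theta_delta_ratio <- ifelse(out$delta_power > 0,
                                  out$theta_power / out$delta_power, NA_real_)
  class(out) <- c("epoch_features", "data.frame")
  attr(out, "epoch_s") <- epoch_s
  out
}

# valley of a bimodal distribution on the log scale; median fallback
bimodal_valley <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(unique(x)) < 5) return(stats::median(x))
  d <- stats::density(log(x), n = 512)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(pk) < 2) return(stats::median(x))
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  lo <- min(pk); hi <- max(pk)
  exp(d$x[lo + which.min(y[lo:hi]) - 1L])
}

#' Score vigilance states from epoch features
#'
#' Rule-based scorer standing in for visual scoring: an epoch is Wake if
#' its EMG RMS exceeds the EMG threshold; otherwise NREM if delta power
#' exceeds the delta threshold; otherwise REM if the theta:delta ratio
#' exceeds the ratio threshold; otherwise NREM. Automatic thresholds are
#' the valley of the bimodal log-feature histogram (median fallback). A REM
#' epoch not preceded within three epochs by NREM or REM is relabeled Wake,
#' since direct wake-to-REM transitions are physiologically inadmissible in
#' healthy rodents.
#'
#' @param features an `"epoch_features"` data.frame.
#' @param thresholds `"auto"` or a named list/vector with `emg`, `delta`,
#'   `theta_delta`.
#' @param start timestamp of the first epoch.
#' @return a [hypnogram()].
#' @export
score_epochs <- function(features, thresholds = "auto",
                         start = "2024-01-01 07:00:00") {
  epoch_s <- attr(features, "epoch_s") %||% 10
  if (identical(thresholds, "auto")) {
    if (nrow(features) * epoch_s < 3600)
      stop("at least 1 h of epochs required for automatic thresholding")
    if (stats::sd(features$emg_rms) == 0 &&
        stats::sd(features$delta_power) == 0)
      stop("features are identical across epochs; no separability")
    thresholds <- list(emg = bimodal_valley(features$emg_rms),
                       delta = bimodal_valley(features$delta_power),
                       theta_delta = bimodal_valley(features$theta_delta_ratio))
  }
  th <- as.list(thresholds)
  lab <- ifelse(features$emg_rms > th$emg, "Wake",
         ifelse(features$delta_power > th$delta, "NREM",
         ifelse(!is.na(features$theta_delta_ratio) &
                  features$theta_delta_ratio > th$theta_delta, "REM", "NREM")))
  # admissibility: REM must be preceded (within 3 epochs) by NREM or REM
  for (i in seq_along(lab)) {
    if (lab[i] == "REM") {
      prev <- lab[max(1, i - 3):max(1, i - 1)]
      if (i == 1L || !any(prev %in% c("NREM", "REM"))) lab[i] <- "Wake"
    }
  }
  hypnogram(lab, epoch_s = epoch_s, start = start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time in each vigilance state per analysis window
#'
#' Tallies minutes per state in hourly windows, subjective dark/light
#' halves, or whole 24-h days. Artifact epochs are excluded from the state
#' columns and reported separately.
#'
#' @param hyp a [hypnogram()].
#' @param schedule a [light_schedule()].
#' @param window `"hourly"`, `"subjective"` (SD = ZT 12-24 / SL = ZT 0-12
#'   halves) or `"24h"`.
#' @return data.frame with one row per window: `window`, `minutes` per
#'   state, `artifact_min`, `window_min`.
#' @export
state_amounts <- function(hyp, schedule,
                          window = c("hourly", "subjective", "24h")) {
  window <- match.arg(window)
  zt <- hyp_zt(hyp, schedule)
  grp <- switch(window,
    hourly = floor(zt),
    subjective = paste0("D", floor(zt / 24) + 1, "_",
                        ifelse(zt %% 24 >= 12, "SD", "SL")),
    "24h" = paste0("day", floor(zt / 24) + 1))
  if (length(unique(grp)) == 0L) stop("hypnogram overlaps no windows")
  states <- c("Wake", "NREM", "REM")
  ug <- unique(grp)
  out <- data.frame(window = as.character(ug))
  for (s in states)
    out[[paste0(tolower(s), "_min")]] <-
      vapply(ug, function(g) sum(hyp$labels == s & grp == g), 0) *
      hyp$epoch_s / 60
  out$artifact_min <- vapply(ug, function(g)
    sum(hyp$labels == "Artifact" & grp == g), 0) * hyp$epoch_s / 60
  out$window_min <- vapply(ug, function(g) sum(grp == g), 0) *
    hyp$epoch_s / 60
  rownames(out) <- NULL
  out
}

#' Subjective dark to subjective light ratio per vigilance state
#'
#' Ratio of minutes spent in each state during (subjective) dark (ZT 12-24)
#' to minutes during (subjective) light (ZT 0-12), aggregated over the
#' whole record. A ratio near 1 indicates a flattened sleep-wake rhythm.
#'
#' @param hyp a [hypnogram()].
#' @param schedule a [light_schedule()].
#' @return named numeric vector over Wake/NREM/REM; `Inf` (flagged by a
#'   warning) where the state is absent in the light phase.
#' @export
dl_ratio <- function(hyp, schedule) {
  zt <- hyp_zt(hyp, schedule) %% 24
  dark <- zt >= 12
  if (!any(dark) || all(dark)) stop("both subjective phases must be present")
  states <- c("Wake", "NREM", "REM")
  r <- vapply(states, function(s) {
    sd_min <- sum(hyp$labels == s & dark)
    sl_min <- sum(hyp$labels == s & !dark)
    if (sl_min == 0 && sd_min > 0) Inf else sd_min / sl_min
  }, 0)
  if (any(is.infinite(r)))
    warning("state absent in subjective light: ratio flagged infinite")
  r
}

#' Decompose a hypnogram into maximal same-state episodes
#'
#' Artifact epochs terminate episodes and are returned as their own runs.
#'
#' @param hyp a [hypnogram()].
#' @return data.frame: `state`, `start_s` (from record start),
#'   `duration_s`.
#' @export
detect_episodes <- function(hyp) {
  r <- rle(hyp$labels)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start_s = (ends - r$lengths) * hyp$epoch_s,
             duration_s = r$lengths * hyp$epoch_s)
}

# printed episode bins are inclusive integer ranges at 10-s resolution, so
# upper edges 30/70/150/... are unambiguous
episode_bin_edges <- function()
  list(labels = c("<=30", "40-70", "80-150", "160-310", "320-630",
                  "640-1270", "1280-2550", ">2550"),
       upper = c(30, 70, 150, 310, 630, 1270, 2550, Inf))

#' Time-weighted episode-duration histogram for one vigilance state
#'
#' Episodes are counted into the eight canonical duration bins (<=30,
#' 40-70, 80-150, 160-310, 320-630, 640-1270, 1280-2550, > 2550 s; since
#' epochs are 10 s no duration can fall between printed edges). The
#' time-weighted percentage of bin k is the summed duration of that bin's
#' episodes as a percent of the state's total time, the standard
#' sleep-fragmentation display.
#'
#' @param episodes data.frame from [detect_episodes()].
#' @param state vigilance state to histogram.
#' @return data.frame of class `"episode_histogram"`: `bin`, `count`,
#'   `time_weighted_pct` (all `NA` pct when the state is absent).
#' @export
episode_histogram <- function(episodes, state) {
  e <- episode_bin_edges()
  dur <- episodes$duration_s[episodes$state == state]
  k <- findInterval(dur, c(0, e$upper[-length(e$upper)] + 1e-9)) # 1..8
  count <- tabulate(k, nbins = 8L)
  tw <- vapply(1:8, function(b) sum(dur[k == b]), 0)
  pct <- if (length(dur)) 100 * tw / sum(dur) else rep(NA_real_, 8)
  out <- data.frame(bin = e$labels, count = count, time_weighted_pct = pct)
  class(out) <- c("episode_histogram", "data.frame")
  attr(out, "state") <- state
  attr(out, "n_episodes") <- length(dur)
  out
}

#' EEG band power per short spectral epoch
#'
#' Hann-tapered FFT power of consecutive epochs (default 5 s) over
#' 0.5-120 Hz, collapsed into 0.5-Hz frequency bins and summed into the six
#' canonical bands. Epochs labeled Artifact, and epochs whose label differs
#' from either neighbor (state transitions), are excluded; their rows are
#' kept with `included = FALSE` and `NA` powers.
#'
#' @param eeg a [regts()] EEG signal; `fs >= 240` Hz required.
#' @param hyp a [hypnogram()]; its epoch length must equal `epoch_s` or be
#'   an integer multiple of it (labels are then replicated).
#' @param epoch_s spectral epoch length, seconds (default 5).
#' @return data.frame of class `"band_power"`: `epoch`, `state`,
#'   `included`, one column per band (uV^2), and `total_power`.
#' @export
spectral_bands <- function(eeg, hyp, epoch_s = 5) {
  fs <- fs_hz(eeg)
  if (fs < 240) stop("fs must be >= 240 Hz for bands up to 120 Hz")
  spe <- as.integer(round(epoch_s * fs))
  n_ep <- length(eeg$values) %/% spe
  rep_k <- hyp$epoch_s / epoch_s
  if (abs(rep_k - round(rep_k)) > 1e-9 || rep_k < 1)
    stop("hypnogram epoch length must be a multiple of the spectral epoch")
  lab <- rep(hyp$labels, each = as.integer(round(rep_k)))[seq_len(n_ep)]
  trans <- transition_epochs(lab)
  bands <- eeg_bands()
  out <- data.frame(epoch = seq_len(n_ep), state = lab,
                    included = !(lab == "Artifact" | trans))
  for (b in bands$band) out[[b]] <- NA_real_
  out$total_power <- NA_real_
  for (i in which(out$included)) {
    idx <- ((i - 1) * spe + 1):(i * spe)
    sp <- epoch_spectrum(eeg$values[idx], fs)
    keep <- sp$freq >= 0.5 & sp$freq <= 120
    f <- sp$freq[keep]; p <- sp$power[keep]
    # collapse to 0.5-Hz bins, then sum bins into bands
    half_bin <- floor((f - 0.5) / 0.5)
    half_lo <- 0.5 + 0.5 * half_bin
    for (b in seq_len(nrow(bands))) {
      in_band <- half_lo >= bands$lo[b] & half_lo < bands$hi[b]
      if (b == nrow(bands)) in_band <- in_band | f == 120
      out[[bands$band[b]]][i] <- sum(p[in_band])
    }
    out$total_power[i] <- sum(p)
  }
  class(out) <- c("band_power", "data.frame")
  attr(out, "epoch_s") <- epoch_s
  out
}

# an epoch is a transition epoch if its label differs from either neighbor
transition_epochs <- function(lab) {
  n <- length(lab)
  if (n == 1L) return(FALSE)
  prev <- c(lab[1], lab[-n]); nxt <- c(lab[-1], lab[n])
  lab != prev | lab != nxt
}

#' Normalize band powers against a reference
#'
#' Expresses each band as a percentage of a reference band power:
#' either a baseline recording from the same subject and same time of day
#' (`reference` = a `"band_power"` table whose per-band means are used, or
#' a named vector), or the record's own 24-h mean per band (`per-24h`
#' normalization, `reference = "per24h"`).
#'
#' @param bands a `"band_power"` data.frame from [spectral_bands()].
#' @param reference `"per24h"`, a named numeric vector of reference powers,
#'   or a `"band_power"` table.
#' @return data.frame with the band columns replaced by percentages
#'   (100 = reference level); zero-reference bands become `NA` with a
#'   warning.
#' @export
normalize_bands <- function(bands, reference = "per24h") {
  bn <- eeg_bands()$band
  ref <- if (identical(reference, "per24h")) {
    colMeans(bands[bands$included, bn, drop = FALSE])
  } else if (inherits(reference, "band_power") || is.data.frame(reference)) {
    colMeans(reference[reference$included, bn, drop = FALSE])
  } else if (is.numeric(reference) && all(bn %in% names(reference))) {
    reference[bn]
  } else stop("missing or invalid reference for band normalization")
  if (any(!is.finite(unlist(ref))))
    stop("reference does not cover the required window")
  out <- bands
  for (b in bn) {
    if (ref[[b]] == 0) {
      warning("zero reference power in band ", b, "; flagged NA")
      out[[b]] <- NA_real_
    } else out[[b]] <- 100 * bands[[b]] / ref[[b]]
  }
  out$total_power <- NULL
  out
}

#' Wake-artifact exclusion rule for spectral analysis
#'
#' A recording window is dropped from spectral analysis when artifact
#' epochs occupy more than 20% of it (strictly more; exactly 20% is kept).
#'
#' @param hyp a [hypnogram()].
#' @param window optional epoch index range `c(first, last)`; default the
#'   whole record.
#' @param max_fraction maximum tolerated artifact time fraction.
#' @return `TRUE` to keep the window, `FALSE` to drop it.
#' @export
artifact_exclusion <- function(hyp, window = NULL, max_fraction = 0.20) {
  lab <- hyp$labels
  if (!is.null(window)) lab <- lab[window[1]:window[2]]
  mean(lab == "Artifact") <= max_fraction
}
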