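#' Rebin a regular time series
#'
#' Aggregates a series into coarser bins, e.g. raw telemetry into the 5-min
#' bins used for rhythm analysis. Counts are summed, temperature-like
#' channels averaged.
#'
#' @param ts a [regts()] series.
#' @param bin_min target bin width in minutes; must be an integer multiple
#'   of the current sampling interval.
#' @param reducer `"sum"` (counts) or `"mean"` (temperature).
#' @return a [regts()] at the new bin width. A trailing incomplete bin is
#'   dropped.
#' @export
rebin <- function(ts, bin_min, reducer = c("sum", "mean")) {
  reducer <- match.arg(reducer)
  bin_s <- bin_min * 60
  k <- bin_s / ts$dt_s
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("bin width must be an integer multiple of the sampling interval")
  k <- as.integer(round(k))
  n_out <- length(ts$values) %/% k
  if (n_out == 0L) stop("series shorter than one bin")
  m <- matrix(ts$values[seq_len(n_out * k)], nrow = k)
  out <- if (reducer == "sum") colSums(m) else colMeans(m)
  regts(out, bin_s, ts$start, ts$units)
}

#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period P the series is folded into columns of N bins
#' over K complete cycles (the trailing incomplete cycle is truncated, so
#' every column holds exactly K samples) and the statistic
#' \deqn{Q_P = \frac{K^2 N \sum_h (M_h - M)^2}{\sum_i (x_i - M)^2}
#'           = \frac{K \sum_h (M_h - M)^2}{\hat\sigma^2}}
#' is computed, where \eqn{M_h} are the column means, \eqn{M} the grand
#' mean and \eqn{\hat\sigma^2} the variance of the folded samples. Under
#' the null of no rhythm \eqn{Q_P} is approximately chi-square with N - 1
#' degrees of freedom, which supplies the per-period significance line. Candidate periods are the integer
#' multiples of the bin width inside `[p_min_h, p_max_h]`, so folding is
#' exact and needs no interpolation.
#'
#' @param ts a [regts()] series spanning at least `2 * p_max_h`.
#' @param p_min_h,p_max_h candidate period range in hours (default 12-36).
#' @param alpha significance level for the chi-square line (default 0.05).
#' @param bonferroni if `TRUE`, divide `alpha` by the number of candidate
#'   periods before taking the quantile (off by default, matching
#'   single-peak reporting).
#' @return object of class `"chisq_periodogram"`: a list with `period_h`,
#'   `qp`, `sig_line`, `df`, `alpha`, `bin_h`.
#' @seealso [select_circadian_period()], [cosinor()]
#' @examples
#' tr <- activity_truth(period_h = 24, seed = 1)
#' ts <- simulate_activity(tr, light_schedule("DD"), days = 10)
#' pg <- chisq_periodogram(ts)
#' select_circadian_period(pg)
#' @export
chisq_periodogram <- function(ts, p_min_h = 12, p_max_h = 36, alpha = 0.05,
                              bonferroni = FALSE) {
  x <- ts$values
  bin_h <- ts$dt_s / 3600
  span_h <- length(x) * bin_h
  if (p_min_h <= 0 || p_max_h <= p_min_h) stop("need 0 < p_min_h < p_max_h")
  if (span_h < 2 * p_max_h)
    stop(sprintf("series spans %.1f h; need at least 2 * p_max_h = %.1f h",
                 span_h, 2 * p_max_h))
  if (stats::var(x) == 0)
    stop("zero-variance series: periodogram statistic undefined")
  n_grid <- seq.int(ceiling(p_min_h / bin_h - 1e-9),
                    floor(p_max_h / bin_h + 1e-9))
  n_grid <- n_grid[n_grid >= 2]
  a_eff <- if (bonferroni) alpha / length(n_grid) else alpha
  qp <- sig <- numeric(length(n_grid))
  for (j in seq_along(n_grid)) {
    N <- n_grid[j]
    K <- length(x) %/% N
    xs <- x[seq_len(K * N)]
    M <- mean(xs)
    Mh <- rowMeans(matrix(xs, nrow = N))
    denom <- sum((xs - M)^2)
    qp[j] <- if (denom == 0) 0 else K^2 * N * sum((Mh - M)^2) / denom
    sig[j] <- stats::qchisq(1 - a_eff, df = N - 1)
  }
  structure(list(period_h = n_grid * bin_h, qp = qp, sig_line = sig,
                 df = n_grid - 1, alpha = alpha, bonferroni = bonferroni,
                 bin_h = bin_h),
            class = "chisq_periodogram")
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat(sprintf("Chi-square periodogram: %d candidate periods, %.2f-%.2f h (grid %.3f h)\n",
              length(x$period_h), min(x$period_h), max(x$period_h), x$bin_h))
  pk <- select_circadian_period(x)
  cat(sprintf("  peak: %.2f h, Qp = %.1f (%.1f above the alpha = %g line)\n",
              pk$period_h, pk$qp, pk$amplitude_above_sig, x$alpha))
  invisible(x)
}

#' @export
plot.chisq_periodogram <- function(x, ...) {
  graphics::plot(x$period_h, x$qp, type = "l", xlab = "period (h)",
                 ylab = expression(Q[P]), ...)
  graphics::lines(x$period_h, x$sig_line, lty = 2, col = "red")
  invisible(x)
}

#' Select the circadian period from a periodogram
#'
#' The period of the largest statistic in the searched range is taken as the
#' circadian period; the height of that peak above its significance line is
#' the rhythmicity amplitude used as a proxy for the degree of circadian
#' rhythmicity. A peak below the line is returned with negative
#' `amplitude_above_sig` and `significant = FALSE`.
#'
#' @param pg a [chisq_periodogram()].
#' @return list of class `"period_peak"`: `period_h`, `qp`,
#'   `amplitude_above_sig`, `significant`, `at_boundary`.
#' @export
select_circadian_period <- function(pg) {
  stopifnot(inherits(pg, "chisq_periodogram"), length(pg$qp) > 0)
  i <- which.max(pg$qp)
  structure(list(period_h = pg$period_h[i], qp = pg$qp[i],
                 amplitude_above_sig = pg$qp[i] - pg$sig_line[i],
                 significant = pg$qp[i] > pg$sig_line[i],
                 at_boundary = i == 1L || i == length(pg$qp)),
            class = "period_peak")
}

#' @export
print.period_peak <- function(x, ...) {
  cat(sprintf("Periodogram peak: %.2f h (Qp %.1f, %s, %+.1f vs significance line)%s\n",
              x$period_h, x$qp,
              if (x$significant) "significant" else "not significant",
              x$amplitude_above_sig,
              if (x$at_boundary) " [at range boundary]" else ""))
  invisible(x)
}

#' Classify a period peak as circadian or not
#'
#' A record counts as circadian-rhythmic when its selected peak is
#' significant and falls inside the circadian range. The default range of
#' 20-27 h is the widest conventional one consistent with classifying both
#' 18.5 h and 27.7 h free-running periods as outside it.
#'
#' @param peak a `"period_peak"` from [select_circadian_period()], or a bare
#'   period in hours (then assumed significant).
#' @param circadian_lo_h,circadian_hi_h inclusive range bounds in hours.
#' @return logical flag.
#' @export
classify_rhythmicity <- function(peak, circadian_lo_h = 20,
                                 circadian_hi_h = 27) {
  if (circadian_lo_h >= circadian_hi_h) stop("need lo < hi")
  if (is.numeric(peak))
    peak <- list(period_h = peak, significant = TRUE)
  isTRUE(peak$significant) &&
    peak$period_h >= circadian_lo_h && peak$period_h <= circadian_hi_h
}

#' Cosinor fit of a single-component cosine rhythm
#'
#' Fits \eqn{x(t) = M + A \cos(2\pi (t - \phi)/P)} by ordinary least squares
#' through the linear parameterization
#' \eqn{M + \beta_c \cos(\omega t) + \beta_s \sin(\omega t)}; the amplitude
#' is \eqn{A = \sqrt{\beta_c^2 + \beta_s^2}} and the acrophase the
#' `atan2`-derived peak time mapped into `[0, P)`. The acrophase is measured
#' in hours from the series start; [acrophase_last_days()] converts it to
#' Zeitgeber time.
#'
#' @param ts a [regts()] series. Spans shorter than two periods are refused
#'   below one period and warned about below two.
#' @param period_h fitted period in hours (default 24).
#' @return An object of class `"cosinor"` with components `mesor`,
#'   `amplitude`, `acrophase_h` (`NA` for a flat fit), `period_h`, `rss`,
#'   and the underlying `lm` fit.
#' @examples
#' t <- seq(0, 48, by = 1/12)[-1]
#' ts <- regts(10 + 3 * cos(2 * pi * (t - 6) / 24), dt_s = 300)
#' coef(cosinor(ts))
#' @export
cosinor <- function(ts, period_h = 24) {
  if (period_h <= 0) stop("'period_h' must be positive")
  span_h <- length(ts$values) * ts$dt_s / 3600
  if (span_h < period_h)
    stop("degenerate design: series spans less than one period")
  if (span_h < 2 * period_h)
    warning("series spans less than two periods; cosinor fit may be unstable")
  t_h <- time_s(ts) / 3600
  w <- 2 * pi / period_h
  fit <- stats::lm(ts$values ~ cos(w * t_h) + sin(w * t_h))
  b <- unname(stats::coef(fit))
  amp <- sqrt(b[2]^2 + b[3]^2)
  acro <- if (amp < .Machine$double.eps^0.5 * max(1, abs(b[1]))) NA_real_
          else (atan2(b[3], b[2]) / w) %% period_h
  structure(list(mesor = b[1], amplitude = amp, acrophase_h = acro,
                 period_h = period_h, rss = sum(stats::resid(fit)^2),
                 lm_fit = fit, n = length(ts$values), dt_s = ts$dt_s,
                 units = ts$units),
            class = "cosinor")
}

#' @export
print.cosinor <- function(x, ...) {
  cat(sprintf("Cosinor fit (period %.2f h, n = %d)\n", x$period_h, x$n))
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase %s h from start\n",
              x$mesor, x$amplitude,
              if (is.na(x$acrophase_h)) "NA (flat)" else sprintf("%.3f", x$acrophase_h)))
  invisible(x)
}

#' @export
coef.cosinor <- function(object, ...) {
  c(mesor = object$mesor, amplitude = object$amplitude,
    acrophase_h = object$acrophase_h)
}

#' @export
summary.cosinor <- function(object, ...) {
  s <- summary(object$lm_fit)
  cat(sprintf("Cosinor fit, period %.2f h, n = %d, RSS %.4g, sigma %.4g\n",
              object$period_h, object$n, object$rss, s$sigma))
  print(coef(object))
  cat("\nLinear parameterization (mesor + bc*cos + bs*sin):\n")
  stats::printCoefmat(s$coefficients)
  invisible(s)
}

#' @export
predict.cosinor <- function(object, t_h = NULL, ...) {
  if (is.null(t_h))
    t_h <- (seq_len(object$n) - 1) * object$dt_s / 3600
  acro <- if (is.na(object$acrophase_h)) 0 else object$acrophase_h
  object$mesor + object$amplitude *
    cos(2 * pi * (t_h - acro) / object$period_h)
}

#' @export
fitted.cosinor <- function(object, ...) stats::fitted(object$lm_fit)

#' @export
residuals.cosinor <- function(object, ...) stats::resid(object$lm_fit)

#' @export
plot.cosinor <- function(x, ...) {
  t_h <- (seq_len(x$n) - 1) * x$dt_s / 3600
  graphics::plot(t_h, stats::fitted(x$lm_fit) + stats::resid(x$lm_fit),
                 pch = ".", xlab = "time (h)", ylab = x$units, ...)
  graphics::lines(t_h, stats::fitted(x$lm_fit), col = "red", lwd = 2)
  invisible(x)
}

#' Acrophase over the trailing days of a record, in Zeitgeber time
#'
#' Fits a 24-h cosinor to the last `n_days` of the series (the standard
#' least-squares phase marker for entrained records) and expresses the
#' acrophase as a ZT hour under the given schedule.
#'
#' @param ts a [regts()] series covering at least `n_days`.
#' @param schedule a [light_schedule()] anchoring ZT0.
#' @param n_days number of trailing days to fit (default 7).
#' @param period_h fitted period (default 24).
#' @return acrophase in ZT hours, `[0, 24)`; `NA` with a warning for a flat
#'   record.
#' @export
acrophase_last_days <- function(ts, schedule, n_days = 7, period_h = 24) {
  span_s <- length(ts$values) * ts$dt_s
  need_s <- n_days * 86400
  if (span_s < need_s)
    stop(sprintf("series spans %.2f days; %d required", span_s / 86400, n_days))
  tail_ts <- window_regts(ts, span_s - need_s, span_s)
  fit <- cosinor(tail_ts, period_h = period_h)
  if (is.na(fit$acrophase_h)) {
    warning("flat record: acrophase undefined")
    return(NA_real_)
  }
  zt_start <- (start_clock_h(tail_ts) - schedule$lights_on) %% 24
  (zt_start + fit$acrophase_h) %% 24
}

#' Phase angle of entrainment
#'
#' The signed difference in hours between the light-dark transition (ZT12)
#' and the rhythm acrophase, wrapped into `(-12, +12]`. Sign convention:
#' positive means the acrophase falls after lights-off (e.g. acrophase ZT18
#' gives +6); an advanced rhythm peaking before lights-off gives a negative
#' angle.
#'
#' @param acrophase_zt_h acrophase in ZT hours, `[0, 24)`.
#' @return phase angle in hours, `(-12, +12]`.
#' @export
phase_angle_entrainment <- function(acrophase_zt_h) {
  if (any(acrophase_zt_h < 0 | acrophase_zt_h >= 24, na.rm = TRUE))
    stop("acrophase must be in [0, 24)")
  w <- (acrophase_zt_h - 12) %% 24
  ifelse(w > 12, w - 24, w)
}

#' Double-plotted actogram matrix
#'
#' Lays a binned record out as one row per day over 48-h columns (each row
#' shows day d followed by day d+1), the standard double-plot layout, for
#' export to external plotting tools.
#'
#' @param ts a [regts()] series whose bin width divides 24 h.
#' @return numeric matrix, rows = days - 1 (or 1 for a single day), columns
#'   = two days of bins; incomplete trailing day padded with `NA`.
#' @export
actogram_matrix <- function(ts) {
  per_day <- 86400 / ts$dt_s
  if (abs(per_day - round(per_day)) > 1e-9)
    stop("bin width must divide 24 h")
  per_day <- as.integer(round(per_day))
  n_days <- ceiling(length(ts$values) / per_day)
  x <- c(ts$values, rep(NA_real_, n_days * per_day - length(ts$values)))
  daymat <- matrix(x, ncol = per_day, byrow = TRUE)
  rows <- max(1L, n_days - 1L)
  out <- matrix(NA_real_, rows, 2L * per_day)
  for (d in seq_len(rows)) {
    out[d, seq_len(per_day)] <- daymat[d, ]
    if (d + 1L <= n_days) out[d, per_day + seq_len(per_day)] <- daymat[d + 1L, ]
  }
  out
}
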