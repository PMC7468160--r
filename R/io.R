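# File formats: plain-text CSV dialects with a small `# key=value` header
# block, YAML for schedules/configs, EDF for raw polysomnography.

read_header_block <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Read a regular time series from CSV
#'
#' Accepts two dialects: `timestamp,value` rows with ISO-8601 timestamps,
#' or `t_min,value` rows with a header block of `# start=`, `# dt_s=`,
#' `# units=` comment lines. Timestamps must be strictly increasing;
#' sampling must be regular up to `jitter_tol` (fractional deviation from
#' the median interval), in which case the sampling interval is taken as
#' the median difference. Larger irregularities are rejected naming the
#' offending timestamp.
#'
#' @param path CSV file path.
#' @param jitter_tol tolerated fractional timestamp jitter (default 0.01).
#' @return a [regts()].
#' @export
read_timeseries <- function(path, jitter_tol = 0.01) {
  kv <- read_header_block(path)
  df <- utils::read.csv(path, comment.char = "#")
  if ("timestamp" %in% names(df)) {
    tt <- as.POSIXct(df$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tt)) stop("unparseable timestamp at row ", which(is.na(tt))[1])
    t_s <- as.numeric(tt) - as.numeric(tt[1])
    start <- tt[1]
  } else if ("t_min" %in% names(df)) {
    t_s <- df$t_min * 60
    start <- as.POSIXct(kv$start %||% "2024-01-01 00:00:00", tz = "UTC")
  } else stop("CSV must have a 'timestamp' or 't_min' column")
  d <- diff(t_s)
  if (any(d <= 0))
    stop("timestamps not strictly increasing at row ", which(d <= 0)[1] + 1)
  dt <- stats::median(d)
  off <- abs(d - dt) / dt
  if (any(off > jitter_tol))
    stop(sprintf("irregular sampling at row %d (interval %.6g s, expected %.6g s)",
                 which(off > jitter_tol)[1] + 1, d[which(off > jitter_tol)[1]], dt))
  if (!is.null(kv$dt_s)) dt <- as.numeric(kv$dt_s)
  regts(df$value, dt, start, kv$units %||% "")
}

#' Write a regular time series to CSV
#'
#' Writes the `t_min,value` dialect with a `# start= / # dt_s= / # units=`
#' header block; [read_timeseries()] round-trips it losslessly.
#'
#' @param ts a [regts()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# start=%s", format(ts$start, "%Y-%m-%d %H:%M:%S")),
               sprintf("# dt_s=%.10g", ts$dt_s),
               sprintf("# units=%s", ts$units),
               "t_min,value"), con)
  writeLines(sprintf("%.10g,%.10g", time_s(ts) / 60, ts$values), con)
  invisible(path)
}

#' Read / write a hypnogram CSV
#'
#' Dialect: header block `# epoch_s=`, `# start=`, then `epoch_index,label`
#' rows.
#'
#' @param path file path.
#' @return [read_hypnogram()]: a [hypnogram()]; [write_hypnogram()]:
#'   `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  kv <- read_header_block(path)
  df <- utils::read.csv(path, comment.char = "#")
  hypnogram(df$label, epoch_s = as.numeric(kv$epoch_s %||% 10),
            start = kv$start %||% "2024-01-01 07:00:00")
}

#' @rdname read_hypnogram
#' @param hyp a [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# epoch_s=%g", hyp$epoch_s),
               sprintf("# start=%s", format(hyp$start, "%Y-%m-%d %H:%M:%S")),
               "epoch_index,label"), con)
  writeLines(sprintf("%d,%s", seq_along(hyp$labels), hyp$labels), con)
  invisible(path)
}

#' Read / write a light schedule as YAML
#'
#' Keys: `mode`, `lights_on`, `blocks` (list of `[light_h, dark_h]`
#' pairs).
#'
#' @param path YAML file path.
#' @return [read_schedule()]: a [light_schedule()].
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  light_schedule(mode = y$mode, lights_on = y$lights_on %||% 7,
                 blocks = if (!is.null(y$blocks))
                   do.call(rbind, y$blocks) else NULL)
}

#' @rdname read_schedule
#' @param schedule a [light_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  yaml::write_yaml(list(mode = schedule$mode,
                        lights_on = schedule$lights_on,
                        blocks = apply(schedule$blocks, 1, as.list,
                                       simplify = FALSE)),
                   path)
  invisible(path)
}

# ---- EDF -------------------------------------------------------------------

edf_pad <- function(x, n) {
  x <- as.character(x)
  paste0(substr(x, 1, n),
         strrep(" ", max(0, n - nchar(substr(x, 1, n)))))
}

#' Read EEG/EMG channels from an EDF file
#'
#' Minimal reader for continuous 16-bit EDF recordings: parses the fixed
#' ASCII header, applies per-channel physical scaling
#' `(digital - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) +
#' phys_min`, and concatenates data records. All requested channels must
#' share one sampling rate.
#'
#' @param path EDF file path.
#' @param channels channel labels to extract (e.g. `c("EEG", "EMG")`).
#' @return named list of [regts()] objects.
#' @export
read_edf <- function(path, channels = c("EEG", "EMG")) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rdn <- function(n) as.numeric(trimws(rd(n)))
  rd(8)                                   # version
  rd(80); rd(80)                          # patient / recording id
  d8 <- trimws(rd(8)); t8 <- trimws(rd(8))
  rdn(8)                                  # header bytes
  rd(44)
  n_rec <- rdn(8); rec_dur <- rdn(8); ns <- as.integer(rdn(4))
  lab <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  unit <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- vapply(seq_len(ns), function(i) rdn(8), 0)
  pmax_ <- vapply(seq_len(ns), function(i) rdn(8), 0)
  dmin_ <- vapply(seq_len(ns), function(i) rdn(8), 0)
  dmax_ <- vapply(seq_len(ns), function(i) rdn(8), 0)
  vapply(seq_len(ns), function(i) rd(80), "")   # prefilter
  spr <- vapply(seq_len(ns), function(i) rdn(8), 0)
  vapply(seq_len(ns), function(i) rd(32), "")
  missing <- setdiff(channels, lab)
  if (length(missing))
    stop("channel(s) not found: ", paste(missing, collapse = ", "),
         "; available: ", paste(lab, collapse = ", "))
  raw_dat <- lapply(seq_len(ns), function(i) vector("list", n_rec))
  for (r in seq_len(n_rec)) for (i in seq_len(ns))
    raw_dat[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2,
                                 signed = TRUE, endian = "little")
  start <- as.POSIXct(paste(d8, t8), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(start)) start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  out <- list()
  for (ch in channels) {
    i <- match(ch, lab)
    dig <- unlist(raw_dat[[i]])
    phys <- (dig - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) +
      pmin_[i]
    out[[ch]] <- regts(phys, rec_dur / spr[i], start, unit[i])
  }
  out
}

#' Write channels to an EDF file
#'
#' Counterpart to [read_edf()]: quantizes each channel to the 16-bit
#' digital range over its physical min/max and writes a continuous EDF
#' recording with `record_s`-second data records.
#'
#' @param channels named list of [regts()] objects sharing one sampling
#'   rate and length.
#' @param path destination path.
#' @param record_s data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(channels, path, record_s = 1) {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  fs <- fs_hz(channels[[1]])
  n <- length(channels[[1]]$values)
  for (ch in channels)
    if (abs(fs_hz(ch) - fs) > 1e-9 || length(ch$values) != n)
      stop("all channels must share sampling rate and length")
  spr <- as.integer(round(fs * record_s))
  n_rec <- n %/% spr
  ns <- length(channels)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr(format(channels[[1]]$start, "%d.%m.%y"), 8)
  wr(format(channels[[1]]$start, "%H.%M.%S"), 8)
  wr(as.character(256 * (ns + 1)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr(sprintf("%g", record_s), 8)
  wr(as.character(ns), 4)
  rng <- lapply(channels, function(ch) {
    lo <- min(ch$values); hi <- max(ch$values)
    if (hi == lo) hi <- lo + 1
    c(lo, hi)
  })
  for (nm in names(channels)) wr(nm, 16)
  for (nm in names(channels)) wr("", 80)
  for (ch in channels) wr(ch$units, 8)
  for (r in rng) wr(sprintf("%.8g", r[1]), 8)
  for (r in rng) wr(sprintf("%.8g", r[2]), 8)
  for (nm in names(channels)) wr("-32768", 8)
  for (nm in names(channels)) wr("32767", 8)
  for (nm in names(channels)) wr("", 80)
  for (nm in names(channels)) wr(as.character(spr), 8)
  for (nm in names(channels)) wr("", 32)
  dig <- mapply(function(ch, r) {
    as.integer(round((ch$values - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  }, channels, rng, SIMPLIFY = FALSE)
  for (rec in seq_len(n_rec)) for (i in seq_len(ns))
    writeBin(dig[[i]][((rec - 1) * spr + 1):(rec * spr)], con, size = 2,
             endian = "little")
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

config_defaults <- function() list(
  periodogram_range_h = c(12, 36),
  alpha = 0.05,
  circadian_range_h = c(20, 27),
  scoring_epoch_s = 10,
  spectral_epoch_s = 5,
  artifact_max_fraction = 0.20,
  zeroing_window_s = 60,
  pre_post_window_s = 10,
  cracm_window_ms = 50,
  cracm_criterion_pct = 50,
  acrophase_last_days = 7,
  seed = 1L)

#' Validated analysis configuration
#'
#' Collects every tunable of the analysis chain with its default: the
#' periodogram search range and significance level, circadian-range
#' bounds, scoring/spectral epoch lengths, the wake-artifact tolerance,
#' photometry windows, the circuit-mapping response window and
#' connectivity criterion, and the seed. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults by name.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (diff(cfg$periodogram_range_h) <= 0 || diff(cfg$circadian_range_h) <= 0)
    stop("ranges must be increasing (lo, hi) pairs")
  if (cfg$artifact_max_fraction < 0 || cfg$artifact_max_fraction > 1)
    stop("artifact_max_fraction must be in [0, 1]")
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname analysis_config
#' @param config an `"analysis_config"`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- pipeline --------------------------------------------------------------

#' Run configured analysis stages over a file manifest
#'
#' Executes the requested stages in order and assembles a self-describing
#' report: each numeric output is accompanied by the configuration that
#' produced it, and identical config + inputs yield identical payloads. A
#' failing stage is recorded as failed without aborting the others.
#'
#' Supported manifest entries:
#' \describe{
#'   \item{rhythm}{`list(input = <timeseries csv>, schedule = <yaml>)` -
#'     periodogram peak, rhythmicity class, cosinor fit, acrophase and
#'     phase angle.}
#'   \item{sleep}{`list(hypnogram = <csv>, schedule = <yaml>)` - state
#'     amounts, D/L ratios, episode histograms.}
#'   \item{cracm}{`list(pulses = <csv t_s,dur_ms>, events = <csv
#'     t_s,amplitude_pA>)` - connectivity summary.}
#'   \item{tracing}{`list(counts = <csv region,count>)` - input
#'     fractions.}
#' }
#'
#' @param config an [analysis_config()].
#' @param manifest named list of stage inputs (see above).
#' @param out optional path for a JSON report.
#' @return report list of class `"chronophys_report"`.
#' @export
run_pipeline <- function(config, manifest, out = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(package_version = as.character(utils::packageVersion("chronophys")),
                 config = unclass(config), seed = config$seed,
                 stages = list())
  run_stage <- function(name, fun) {
    res <- tryCatch(list(status = "ok", output = fun()),
                    error = function(e) list(status = "failed",
                                             message = conditionMessage(e)))
    report$stages[[name]] <<- res
  }
  if (!is.null(manifest$rhythm)) run_stage("rhythm", function() {
    ts <- read_timeseries(manifest$rhythm$input)
    sch <- read_schedule(manifest$rhythm$schedule)
    pg <- chisq_periodogram(ts, config$periodogram_range_h[1],
                            config$periodogram_range_h[2], config$alpha)
    pk <- select_circadian_period(pg)
    fit <- cosinor(ts, period_h = pk$period_h)
    acro <- tryCatch(acrophase_last_days(ts, sch,
                                         n_days = config$acrophase_last_days),
                     error = function(e) NA_real_)
    list(peak = unclass(pk),
         is_circadian = classify_rhythmicity(pk, config$circadian_range_h[1],
                                             config$circadian_range_h[2]),
         cosinor = list(mesor = fit$mesor, amplitude = fit$amplitude,
                        acrophase_h = fit$acrophase_h,
                        period_h = fit$period_h, rss = fit$rss),
         acrophase_zt_h = acro,
         phase_angle_h = if (is.na(acro)) NA_real_ else
           phase_angle_entrainment(acro),
         units = ts$units)
  })
  if (!is.null(manifest$sleep)) run_stage("sleep", function() {
    hyp <- read_hypnogram(manifest$sleep$hypnogram)
    sch <- read_schedule(manifest$sleep$schedule)
    eps <- detect_episodes(hyp)
    list(amounts_hourly = state_amounts(hyp, sch, "hourly"),
         dl_ratio = as.list(dl_ratio(hyp, sch)),
         episode_histograms = lapply(
           stats::setNames(nm = c("Wake", "NREM", "REM")),
           function(s) episode_histogram(eps, s)))
  })
  if (!is.null(manifest$cracm)) run_stage("cracm", function() {
    pulses <- utils::read.csv(manifest$cracm$pulses)
    events <- utils::read.csv(manifest$cracm$events)
    proto <- stim_protocol("single", pulse_onsets_s = pulses$t_s,
                           pulse_dur_ms = pulses$dur_ms[1] %||% 10)
    sess <- stim_session(proto, events)
    res <- cracm_connectivity(sess, config$cracm_window_ms,
                              config$cracm_criterion_pct)
    list(response_prob_pct = res$response_prob,
         baseline_prob_pct = res$baseline_prob, connected = res$connected,
         latency_mean_ms = res$latency$mean_ms,
         amplitude_mean_pA = res$amplitude$mean_pA)
  })
  if (!is.null(manifest$tracing)) run_stage("tracing", function() {
    counts <- utils::read.csv(manifest$tracing$counts)
    input_fraction(counts)
  })
  class(report) <- "chronophys_report"
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.chronophys_report <- function(x, ...) {
  cat("chronophys pipeline report (version", x$package_version, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  stage %-8s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
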