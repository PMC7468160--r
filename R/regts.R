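#' Regularly sampled physiological time series
#'
#' Container for a uniformly sampled channel (activity counts, body
#' temperature, wheel rotations, fluorescence, voltage). Sampling is fully
#' described by the start timestamp and the sampling interval `dt_s`;
#' missing values are not permitted (gaps must be imputed explicitly before
#' construction, see [read_timeseries()]).
#'
#' @param values numeric vector of samples.
#' @param dt_s sampling interval in seconds (> 0).
#' @param start timestamp of the first sample. A `POSIXct`, or a string
#'   parseable by `as.POSIXct()`. Timestamps are treated as timezone-naive
#'   local clock time.
#' @param units free-text unit label (e.g. `"counts"`, `"degC"`, `"uV"`).
#' @return An object of class `"regts"`.
#' @examples
#' ts <- regts(rpois(288, 5), dt_s = 300, units = "counts")
#' ts
#' @export
regts <- function(values, dt_s, start = "2024-01-01 07:00:00", units = "") {
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric vector")
  if (anyNA(values))
    stop("series contains missing values; impute or reject gaps before construction")
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0)
    stop("'dt_s' must be a single positive number")
  if (!inherits(start, "POSIXct"))
    start <- as.POSIXct(start, tz = "UTC")
  structure(
    list(values = as.numeric(values), dt_s = as.numeric(dt_s),
         start = start, units = as.character(units)[1L]),
    class = "regts")
}

#' @export
print.regts <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("Regular time series: %d samples @ %g s (%.2f h span)\n",
              n, x$dt_s, n * x$dt_s / 3600))
  cat(sprintf("  start: %s   units: %s\n",
              format(x$start, "%Y-%m-%d %H:%M:%S"),
              if (nzchar(x$units)) x$units else "<none>"))
  cat("  values: ", paste(signif(utils::head(x$values, 6), 4), collapse = ", "),
      if (n > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.regts <- function(x) length(x$values)

# sampling frequency in Hz
fs_hz <- function(ts) 1 / ts$dt_s

# elapsed time of each sample from the series start, seconds
time_s <- function(ts) (seq_along(ts$values) - 1) * ts$dt_s

# clock hour-of-day of the series start (0-24)
start_clock_h <- function(ts) {
  lt <- as.POSIXlt(ts$start)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Extract a time window from a series
#'
#' @param ts a [regts()] series.
#' @param from,to window bounds in seconds from the series start, half-open
#'   `[from, to)`.
#' @return the windowed `regts`.
#' @export
window_regts <- function(ts, from, to) {
  t <- time_s(ts)
  keep <- t >= from & t < to
  if (!any(keep)) stop("requested window contains no samples")
  regts(ts$values[keep], ts$dt_s, ts$start + from, ts$units)
}

#' Light schedule (LD, DD or skeleton photoperiod)
#'
#' Describes the lighting regime and anchors Zeitgeber time: ZT0 is
#' lights-on, ZT12 lights-off under a 12:12 cycle. Under constant darkness
#' (DD) the projected (subjective) ZT is extrapolated at 24.0 h from the
#' last light-dark anchor, so `lights_on` still sets the phase reference.
#'
#' @param mode `"LD"`, `"DD"` or `"SKP"` (skeleton photoperiod).
#' @param lights_on clock hour of lights-on (ZT0), default 7 (7 A.M.).
#' @param blocks matrix or list of `(light_h, dark_h)` pairs laid out in
#'   order from ZT0; must sum to 24 h. Defaults: 12:12 for LD, 1:11:1:11
#'   for SKP. Ignored (all dark) for DD, but retained as the projected
#'   anchor.
#' @return An object of class `"light_schedule"`.
#' @examples
#' light_schedule("LD")                  # 12:12, lights-on 07:00
#' light_schedule("SKP")                 # 1:11:1:11 skeleton photoperiod
#' @export
light_schedule <- function(mode = c("LD", "DD", "SKP"), lights_on = 7,
                           blocks = NULL) {
  mode <- match.arg(mode)
  if (is.null(blocks))
    blocks <- switch(mode,
                     LD = rbind(c(12, 12)),
                     DD = rbind(c(12, 12)),
                     SKP = rbind(c(1, 11), c(1, 11)))
  blocks <- matrix(unlist(blocks), ncol = 2, byrow = !is.matrix(blocks))
  if (abs(sum(blocks) - 24) > 1e-9)
    stop("photoperiod blocks must sum to 24 h")
  if (!is.numeric(lights_on) || lights_on < 0 || lights_on >= 24)
    stop("'lights_on' must be a clock hour in [0, 24)")
  structure(list(mode = mode, lights_on = lights_on, blocks = blocks),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule: %s, lights-on %02d:%02d (ZT0)\n", x$mode,
              floor(x$lights_on), round((x$lights_on %% 1) * 60)))
  if (x$mode != "DD")
    cat("  blocks (light:dark h): ",
        paste(apply(x$blocks, 1, function(b) sprintf("%g:%g", b[1], b[2])),
              collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Zeitgeber time of samples in a series
#'
#' Continuous (unwrapped) ZT hours for every sample of `ts` under
#' `schedule`; under DD this is projected/subjective ZT.
#'
#' @param ts a [regts()] series.
#' @param schedule a [light_schedule()].
#' @return numeric vector, hours since the ZT0 preceding the series start.
#' @export
zt_hours <- function(ts, schedule) {
  zt0 <- (start_clock_h(ts) - schedule$lights_on) %% 24
  zt0 + time_s(ts) / 3600
}

#' Lights-on indicator at given Zeitgeber times
#'
#' @param schedule a [light_schedule()].
#' @param zt_h numeric ZT hours (any real; wrapped modulo 24).
#' @return logical vector, `TRUE` where lights are on. Always `FALSE` in DD.
#' @export
is_light <- function(schedule, zt_h) {
  if (schedule$mode == "DD") return(rep(FALSE, length(zt_h)))
  z <- zt_h %% 24
  edges <- cumsum(as.vector(t(schedule$blocks)))  # light/dark boundaries
  starts <- c(0, utils::head(edges, -1))
  light <- rep(FALSE, length(z))
  for (k in seq(1, length(starts), by = 2))       # odd segments are light
    light <- light | (z >= starts[k] & z < edges[k])
  light
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generators route randomness through this
# so that identical (truth, seed) pairs reproduce identical output without
# touching global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
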