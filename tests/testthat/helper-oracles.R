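# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: the periodogram oracle folds by explicit
# per-column indexing, the kernel rise point is found by root-finding on
# the closed-form waveform.

# Brute-force chi-square periodogram score for one candidate column count N:
# fold x into N phase columns by direct indexing and apply
# Qp = K * sum_h (M_h - M)^2 / (sum_i (x_i - M)^2 / (K N)).
brute_qp <- function(x, N) {
  K <- length(x) %/% N
  xs <- x[seq_len(K * N)]
  M <- mean(xs)
  col_means <- numeric(N)
  for (h in seq_len(N))
    col_means[h] <- mean(xs[h + N * (0:(K - 1))])
  K^2 * N * sum((col_means - M)^2) / sum((xs - M)^2)
}

# closed-form 5%-of-peak rise time (ms) of the difference-of-exponentials
# IPSC waveform with the given rise/decay constants (ms)
analytic_rise5_ms <- function(rise_ms = 1, decay_ms = 10) {
  k <- function(t) exp(-t / decay_ms) - exp(-t / rise_ms)
  tp <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  target <- 0.05 * k(tp)
  stats::uniroot(function(t) k(t) - target, c(1e-6, tp))$root
}

# default three-state demo hypnogram used by several tests
demo_hypnogram <- function(n_each = 40, epoch_s = 10)
  hypnogram(rep(c("Wake", "NREM", "REM"), each = n_each), epoch_s = epoch_s)

# unit-amplitude sine as an EEG-like regts
sine_ts <- function(freq_hz, dur_s, fs = 250)
  regts(sin(2 * pi * freq_hz * (0:(dur_s * fs - 1)) / fs), 1 / fs,
        units = "uV")
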