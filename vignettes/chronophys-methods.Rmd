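---
title: "Methods: rhythm, sleep, photometry and circuit-mapping analysis in chronophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm, sleep, photometry and circuit-mapping analysis in chronophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronophys)
```

chronophys implements the quantitative chain of a multi-modal circadian
neurophysiology study: rhythm statistics on telemetry and wheel records,
vigilance-state architecture and EEG spectra, fiber-photometry calcium
traces, optogenetically evoked synaptic currents, and retrograde-tracing
counts. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic generators do and do not
emulate.

## Time conventions

All timestamps are timezone-naive local clock time. Zeitgeber time (ZT)
anchors phase: ZT0 is lights-on, ZT12 lights-off under a 12:12 cycle
(`light_schedule("LD", lights_on = 7)` places ZT0 at 07:00). Under
constant darkness the projected (subjective) ZT is extrapolated at
exactly 24.0 h from the last light-dark anchor; subjective dark is ZT
12–24 and subjective light ZT 0–12. Windows are half-open `[start, end)`
throughout.

## Chi-square periodogram

For a candidate period $P$ spanning $N$ bins, the record is folded into
$N$ phase columns over $K = \lfloor n/N \rfloor$ complete cycles and
scored as
$$Q_P = \frac{K^2 N \sum_h (M_h - \bar x)^2}{\sum_i (x_i - \bar x)^2}
      = \frac{K \sum_h (M_h - \bar x)^2}{\hat\sigma^2},$$
the Sokolove–Bushell normalization under which $Q_P$ is asymptotically
$\chi^2_{N-1}$ when no rhythm is present. The significance line is the
$1-\alpha$ chi-square quantile per candidate (default $\alpha = 0.05$;
an optional Bonferroni correction across candidates is off by default,
matching single-peak reporting practice).

Numerical choices:

* The candidate grid is the set of integer multiples of the bin width
  inside the search range (default 12–36 h), so folding is exact and
  needs no interpolation. The grid resolution therefore equals the bin
  width (5-min bins give 1/12-h steps).
* The trailing incomplete cycle at each candidate is truncated, keeping
  every phase column at exactly $K$ samples (balanced occupancy).
* A zero-variance record is rejected: the statistic is undefined.
* $Q_P$ is invariant to affine transforms of the record, so counts,
  temperatures and wheel revolutions are treated identically.

The largest peak in range is selected as the circadian period; its height
above the significance line serves as a rhythmicity amplitude. A peak is
classified circadian when it is significant *and* falls inside a
configurable circadian range. The default range of 20–27 h is our
choice of the widest conventional band that still classifies free-running
periods of 18.5 h and 27.7 h as outside it; both bounds are exposed in
`classify_rhythmicity()` and `analysis_config()`.

## Cosinor rhythmometry and the phase angle of entrainment

`cosinor()` fits $x(t) = M + A\cos(2\pi(t-\phi)/P)$ by ordinary least
squares via the linear parameterization $M + \beta_c\cos\omega t +
\beta_s\sin\omega t$, with $A = \sqrt{\beta_c^2+\beta_s^2}$ and $\phi$
the `atan2` solution mapped into $[0, P)$. It is a classed model object
with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and
`plot` methods. Spans below one period are refused; spans below two
periods fit with a warning. A flat record returns amplitude 0 with an
undefined (`NA`) acrophase.

The entrained phase marker is `acrophase_last_days()`: a 24-h cosinor on
the trailing 7 days, expressed in ZT. The phase angle of entrainment is
$$\Psi = \mathrm{wrap}_{(-12,\,+12]}(\phi_{ZT} - 12),$$
the signed difference between lights-off and the acrophase. The sign
convention is ours and documented rather than inherited: positive means
the rhythm peaks *after* lights-off (ZT18 gives $+6$), so an advanced
rhythm has a smaller or negative $\Psi$.

## Vigilance scoring and sleep architecture

`compute_epoch_features()` reduces EEG/EMG to per-epoch (default 10 s)
features: EMG root-mean-square, and delta (0.5–5 Hz) and theta (5–9 Hz)
power by Hann-tapered periodogram integration. `score_epochs()` applies a
fixed rule cascade — Wake if EMG RMS exceeds its threshold, else NREM if
delta power exceeds its threshold, else REM if the theta:delta ratio
exceeds its threshold, else NREM — followed by an admissibility pass that
relabels as Wake any REM epoch not preceded within three epochs by NREM
or REM, since direct wake-to-REM transitions do not occur in healthy
rodents.

Automatic thresholds are the valley between the two largest modes of the
log-feature density, falling back to the median when the distribution is
not bimodal. This replaces a human scorer and is an approximation:
explicit thresholds can always be supplied. At least one hour of epochs
is required before auto-thresholding is attempted.

Architecture summaries: `state_amounts()` tallies minutes per state in
hourly, subjective-phase, or 24-h windows, excluding artifact epochs from
the state columns and reporting them separately so that state + artifact
time always equals window length exactly. `dl_ratio()` divides subjective
dark by subjective light minutes per state (flagging division by zero as
infinite). `detect_episodes()` returns maximal same-state runs (artifact
epochs terminate episodes), and `episode_histogram()` bins their
durations into the eight canonical fragmentation bins. The printed bin
edges leave 10-s gaps (30 → 40 s, etc.); since epochs are 10 s no
duration can fall inside a gap, and we treat the bins as inclusive
integer ranges at 10-s resolution (30 s belongs to the first bin). The
time-weighted percentage of a bin is the summed duration it holds as a
percent of the state's total time, so the percentages sum to 100 whenever
the state occurs.

## EEG band power

`spectral_bands()` computes per 5-s epoch a Hann-windowed FFT power
spectrum over 0.5–120 Hz, collapses it into 0.5-Hz frequency bins, and
sums the bins into six bands (delta 0.5–5, theta 5–9, sigma 9–15, beta
15–30, low gamma 30–60, high gamma 60–120 Hz; half-open on the right
except the last). Because the bands partition the analyzed range, their
sum equals the total 0.5–120 Hz power per epoch to floating tolerance — a
property the tests assert. A single Hann taper per epoch is the minimal,
standard leakage control; 5-s epochs give 0.2-Hz native resolution.

Exclusions: epochs labeled Artifact are omitted, as are automatically
detected transition epochs (label differing from either neighbor), our
stand-in for visual identification of mixed-state epochs. A whole window
is dropped from spectral analysis only when artifact time exceeds 20 % of
it — strictly more, so exactly 20 % is kept. `normalize_bands()` expresses
band power as a percentage of either a baseline recording's per-band
means (same subject, same time of day) or the record's own 24-h mean.

## Fiber photometry

The processing order is: downsample to 1 Hz (non-overlapping window
means), fit the bleaching baseline, form ΔF/F, z-score.

The baseline is the two-term exponential
$F_0(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c$ — the standard
photobleaching model with a slow and a fast component — fitted by
Levenberg–Marquardt (`minpack.lm::nlsLM`) from four starts over
log-spaced time constants, with $\tau_1 > \tau_2$ enforced by relabeling.
If no two-term start converges, a single exponential is fitted with a
warning; a near-constant trace short-circuits to the degenerate
$a_1 = a_2 = 0$, $F_0 = c$ solution. ΔF/F is $(F_t - F_0)/F_0$, which
requires a positive baseline. Z-scoring uses the whole recording segment
by default; whether per-condition segments are preferable is
study-specific, so the segment is simply whatever trace is passed in.

Transition analysis zeroes the trace by the median of the 60 s preceding
the transition (an idempotent operation), `pre_post_response()` compares
10-s pre/post means with a two-tailed paired t-test across sessions
(zero-variance differences are flagged rather than tested), and
`align_events()` returns the event-aligned matrix with mean ± s.e.m. The
405-nm control channel is used for *rejection* only, never for
regression-based correction: `motion_artifact_check()` drops a session
when the detrended signal–control correlation exceeds 0.7 in more than
half of the 30-s windows. Both the threshold and the window are exposed,
since "moving in parallel" is inherently a qualitative criterion.

## Circuit-mapping statistics

Connectivity is decided from event probabilities: the response
probability is the percentage of pulses with at least one IPSC in the
half-open window (onset, onset + 50 ms] — an event exactly at the onset
counts as baseline — and the baseline probability is the same statistic
in the matched window ending at each onset. The baseline window placement
is our choice (the natural matched comparator); pulses must be separated
by more than twice the window so the two never overlap. A cell is
connected when its response probability strictly exceeds 50 %.

Latency is measured to the 5 %-of-peak rise point of the first IPSC:
with a rendered trace, the first sample at or above 5 % of the event's
peak deflection walking back from the peak; with an event list only, the
event onset is used and the result flagged onset-based (the two differ by
a kernel-dependent constant). Amplitude summaries average first-event
peaks over responsive pulses. The event detector — local maxima of the
outward deflection from the trace median above a threshold, merged under
a refractory interval, with onsets at the first threshold crossing — is
deliberately simple and fully parameterized; it replaces proprietary
detection software, and no parity with any particular tool is claimed.

## Synthetic data generators

Every generator is a pure function of a truth object carrying its own
seed; randomness flows through one local RNG stream and the caller's
stream is untouched, so identical (truth, seed) pairs are bitwise
reproducible.

* **Activity/temperature** (`simulate_activity`): rectified
  cosine-plus-Gaussian-noise in ZT, multiplicative masking on lights-on
  bins (the simplest mechanism that reproduces light suppression of
  nocturnal activity), and an arrhythmic mode that phase-randomizes the
  rhythmic component by shuffling it across bins — preserving the
  marginal distribution while destroying periodicity, which gives the
  periodogram a matched-power null.
* **Hypnogram** (`simulate_hypnogram`): a Markov chain over
  Wake/NREM/REM with separate transition matrices for the subjective
  dark and light phases. `transition_matrix()` builds matrices from mean
  episode durations with a fixed exit structure under which the
  stationary wake occupancy is $d_W/(d_W + d_N + (1-q)d_R)$, making
  occupancy ratios between phases exactly designable; the default truth
  (132-s dark vs 44-s light wake episodes) realizes a 2:1 dark:light
  wake bias with mouse-like short episodes.
* **EEG/EMG** (`simulate_eeg_emg`): per-band FFT-masked Gaussian noise
  scaled epoch-by-epoch to each state's band-power profile, plus
  state-scaled white-noise EMG. The default profiles make NREM
  delta-dominated, REM theta-dominated with minimal muscle tone, and
  Wake broadband with high EMG.
* **Photometry** (`simulate_photometry`): bleaching baseline ×
  (tonic + difference-of-exponentials transient kernels) + noise, with
  movement bumps shared sample-for-sample with a control channel that
  carries no transients.
* **CRACM** (`simulate_cracm`): per-pulse Bernoulli evoked events at
  jittered latency on top of a Poisson spontaneous train, with Gaussian
  amplitudes, and optionally a rendered current trace of summed
  difference-of-exponentials IPSC waveforms (default 1-ms rise / 10-ms
  decay — source kinetics are unpublished, so these are conventional
  values and configurable).

What the generators do **not** emulate — and hence what passing tests do
not show about real data: EEG has no 1/f background, no spindles or
micro-arousals; hypnograms have no ultradian structure beyond the
two-phase Markov process (no quantitative description of the source
animals' ultradian structure exists, so defaults were chosen for
testability, not fidelity); photometry motion artifacts are smooth bumps
rather than hemodynamic or fiber-bending transients; IPSC kinetics are
fixed within a session. Scorer accuracy of ~100 % on default profiles
reflects their deliberate separability; real EEG overlaps far more.

## Problem sizes and tolerances used in the tests

The suite verifies: exact equality of the production periodogram with a
brute-force fold-and-score oracle on 20 random series of 2–3 days at
30-min bins; ≥90 % period recovery within ±0.25 h over 50 simulations of
10 days at signal-to-noise 1; machine-precision cosinor recovery on
noiseless cosines; ≥95 % scoring accuracy on 20 one-hour generated
recordings at 250 Hz; exact time conservation and the hand-enumerated
20/50/100-s episode-histogram example (11.76/29.41/58.82 %); band-power
partition to 1e-9 relative; two-exponential recovery to 1e-3 relative on
noiseless 30-min traces; binomial behavior of evoked probabilities over
200 seeded cells at 30 trials; latency agreement with the closed-form
5 %-rise point within one sample at 5 kHz; and input-fraction
normalization. These sizes keep the full suite around two minutes on one
CPU while leaving each statistical check several standard errors of
headroom.

## Known limitations

* Only Lomb–Scargle-free, fold-based periodogram analysis is provided;
  no wavelet or onset-based phase markers.
* The scorer is a transparent rule cascade, not a trained classifier;
  it is not intended to match human scoring on real recordings.
* EDF support covers continuous 16-bit recordings with one sampling rate
  per requested channel set (no EDF+ annotations, no discontinuous
  files).
* Exact numeric parity with proprietary analysis suites (ClockLab,
  SleepSign, MiniAnalysis) is not claimed anywhere; their internal
  normalizations and detection settings are unpublished.
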