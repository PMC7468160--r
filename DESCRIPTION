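Package: chronophys
Title: Circadian Rhythm, Sleep Architecture, Photometry and Circuit-Mapping
    Statistics for Rodent Neurophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for multi-modal rodent circadian neurophysiology
    recordings. Provides chi-square periodogram rhythm detection and period
    selection, cosinor rhythmometry (mesor, amplitude, acrophase) and the
    phase angle of entrainment for locomotor activity, body temperature and
    wheel-running records; rule-based vigilance-state scoring from EEG/EMG
    features with sleep-architecture summaries (hourly amounts, subjective
    dark/light ratios, time-weighted episode-duration histograms) and EEG
    spectral band-power analysis; fiber-photometry trace processing
    (two-exponential bleach correction, dF/F, z-scoring, event alignment and
    pre/post light-pulse tests); optogenetic circuit-mapping connectivity
    statistics (evoked-IPSC probability, latency at the 5 percent rise point,
    amplitude summaries); and retrograde-tracing input-fraction
    quantification. Seeded synthetic-data generators for every modality make
    each stage verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
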