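Package: gaitmod
Title: Gait-Phase-Locked Modulation Analysis of Deep-Brain Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of rhythmic gait-phase-locked modulation of oscillatory
    activity in deep-brain local field potentials (LFPs), as recorded from
    externalized deep-brain-stimulation electrodes during stepping or walking.
    Provides bipolar re-referencing and zero-phase Butterworth filtering,
    complex Morlet time-frequency decomposition, percent-normalized power
    spectra and imaginary LFP-EEG coherence, gait-phase reconstruction from
    force-plate or trunk-accelerometer traces, phase-binned power modulograms
    with a Kullback-Leibler modulation index, within-cycle phase-shuffle
    cluster-based permutation statistics, exact small-sample Wilcoxon and
    Spearman tests, and an autoregressive hidden Markov model of recurring
    LFP states with phase-occupancy histograms and K-medoids clustering.
    Includes a synthetic stepping-session generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    cluster,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
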