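Package: oscrep
Title: Oscillatory Correlates of Discrete Auditory Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking auditory-cortex
    oscillatory activity to the capacity to form discrete auditory
    representations. Provides a synthetic virtual-sensor generator for
    burst-counting experiments (1/f background, stimulus-entrained induced
    oscillations, evoked transients, gamma-band phase/amplitude states
    coupled to trial success), a Hilbert filter-bank time-frequency
    decomposition (3-100 Hz, zero-phase Butterworth bands), circular
    statistics (Rayleigh, Watson-Williams, Watson's U2 with permutation
    null), JZS Bayes factors from t-statistics, Chauvenet outlier
    exclusion, within-subject ANCOVA, repeated-measures ANOVA, and a
    maximum-cluster-mass permutation engine over time-frequency maps,
    together with the three analysis stages they support: an
    amplitude-spectrum/behaviour correlation, a matched/unmatched
    entrainment contrast, and a successful/unsuccessful trial contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    arrow
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
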