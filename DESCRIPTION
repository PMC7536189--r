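Package: somnotools
Title: Rodent Sleep EEG Architecture, NREM Event Detection,
    Phase-Amplitude Coupling and Water-Maze Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@somnotools.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chronic mouse EEG/EMG sleep recordings
    combined with Morris water maze testing. Provides rule-based sleep
    staging of 4-s epochs into wake, NREM and REM sleep; sleep
    macrostructure metrics (total sleep time, stage durations, episode
    statistics, arousal index); detection of NREM slow oscillations by
    zero-crossing segmentation with percentile amplitude criteria and of
    sleep spindles by Hilbert-envelope thresholding; slow-oscillation to
    spindle-band phase-amplitude coupling quantified with an entropy-based
    modulation index; water-maze trial metrics (route efficiency, time to
    target, quadrant occupancy) with a seven-category search-strategy
    classifier and 0-3 point strategy ranking; a statistical battery
    (paired/unpaired t-tests, one-way repeated-measures ANOVA with
    Mauchly/Greenhouse-Geisser handling, Pearson correlation,
    Shapiro-Wilk, Bonferroni adjustment); and a synthetic-data generator
    producing ground-truth hypnograms, EEG/EMG signals with embedded
    events and controllable coupling, and swim trajectories for seven
    search-strategy archetypes. Recordings are read and written in
    European Data Format (EDF) or plain columnar text.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
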