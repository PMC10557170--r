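Package: spindlepower
Title: Sleep Spindle Detection, Sigma Coherence, and Simulated
    Clinical-Trial Power for Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies sleep spindle activity in stage-2 NREM sleep EEG
    two ways -- sigma-band (10-16 Hz) power and C3-C4 magnitude coherence
    computed over all NREM2 epochs, and the same metrics restricted to
    events found by a Morlet-wavelet spindle detector -- and compares the
    sample sizes the two metric families need to demonstrate a paired
    longitudinal decline via subsampled simulated clinical trials. Ships a
    synthetic sleep-EEG cohort generator (1/f background, Hann-windowed
    spindle bursts with controllable inter-channel coherence, paired
    baseline/follow-up visits) so the whole pipeline is testable without
    polysomnography data, plus EDF and hypnogram readers/writers so real
    recordings can be analysed with the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
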