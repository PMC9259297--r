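Package: eegselect
Title: Evolutionary Feature Selection for EEG Event Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for multichannel EEG event detection.
    A genetic algorithm with a Gray-coded mixed representation searches jointly
    over sliding-window overlap, active channels, and per-channel sample
    points; candidate subsets are scored by the validation F1 of a compact
    pyramid-shaped multilayer perceptron trained on event-centred windows.
    Includes IIR preprocessing (mains notch and 1-12 Hz band-pass), min-max
    channel normalization, event-based recording splits, sliding-window
    segmentation, confusion-matrix metrics, a synthetic EEG generator with
    ground-truth eye-blink artifacts, and drivers for multi-run feature
    extraction and held-out generalization experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
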