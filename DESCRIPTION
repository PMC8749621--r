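Package: ppgcond
Title: Motion-Artifact Conditioning of Wrist PPG Signals with Small LSTM Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for conditioning motion-corrupted photoplethysmography (PPG)
    signals recorded on the wrist together with three-axis accelerometer
    channels. Provides a synthetic-record generator with known ground-truth
    peak times, construction of ideal target waveforms from peak annotations
    (gap validation, linear interval interpolation, bottom-flattened cosine
    synthesis), segmentation of normalized records into strided training
    sequences, a small self-contained LSTM network (batched forward pass,
    backpropagation through time, Adam) trained to predict the clean PPG
    value from recent PPG and acceleration samples, zero-phase Butterworth
    band-pass filtering, peak detection and sliding-window heart-rate
    mean-absolute-error evaluation, and an analytic operation-count model
    of the per-inference computational cost of each network variant.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
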