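Package: spikewire
Title: Dual-Path Neural Signal Separation, Spike Compression, and Telemetry Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and analysis toolkit for the embedded
    signal-processing chain of wireless multimodal electrophysiology
    platforms. Generates ground-truthed synthetic action-potential (AP),
    local-field-potential (LFP) and electromyography (EMG) mixtures;
    emulates an analog front-end with 16-bit quantization; separates AP
    from LFP/EMG with symmetric Kaiser-window FIR filters executed through
    a 32-channel time-multiplexed datapath under an explicit clock-cycle
    budget; detects spikes with an adaptive (robust-sigma) threshold;
    compresses 48-sample snippets with a 4-level orthogonal discrete
    wavelet transform into a fixed 184-bit budget; serializes both streams
    into 28-byte telemetry packets; reconstructs recordings at the base
    station; and provides the downstream analyses (PCA + k-means spike
    sorting, 2-norm normalized band powers, binned firing rates,
    stimulation-gated thresholding) together with data-rate and combined
    data-reduction-ratio accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
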