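Package: calstream
Title: Streaming Analysis of Two-Photon Calcium Imaging with Holographic
    Stimulation Targeting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless real-time analysis engine for two-photon calcium
    imaging experiments. Reads raw-binary or TIF frame streams as they are
    written by microscope acquisition software, corrects x-y drift by
    subpixel discrete-Fourier-transform registration, extracts ring-ROI
    somatic fluorescence with annulus-based neuropil correction, computes
    sliding-window baselines and relative fluorescence (dF/F0), and runs
    multi-timescale downstream analysis: pairwise-correlation functional
    networks (minimum spanning tree or thresholded) with degree ranking,
    shift-surrogate tests for higher-order spiking synchrony, and
    stimulus-locked receptive-field / best-frequency tuning. A
    Gerchberg-Saxton module computes spatial-light-modulator phase masks
    (disk or optical-vortex beamlets) for informed photostimulation
    targeting against a virtual SLM. A synthetic-movie generator with full
    ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
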