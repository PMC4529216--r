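Package: frfres
Title: Formant Receptive Fields and Neural Frequency Resolution by
    Cross-Validated Kernel Smoothing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how finely cortical firing rates resolve
    formant frequencies. Synthesizes two-formant pulse-resonance stimulus
    banks, detects spikes in extracellular voltage traces by bandpass
    filtering and negative-threshold crossing, builds formant receptive
    fields (FRFs) from windowed spike counts, screens recording sites with a
    quadrant-based Kruskal-Wallis inclusion test, and estimates the
    frequency-resolution parameter sigma as the bandwidth of the 2-D
    Gaussian smoothing kernel that minimizes cross-validated prediction
    error. Includes a linear-nonlinear-Poisson synthetic data generator so
    every pipeline stage can be exercised and validated without recordings,
    plus population-level summaries and group comparisons of per-site
    resolution estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
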