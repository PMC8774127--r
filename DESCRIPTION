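Package: neurocouple
Title: Structure-Function Coupling of Brain Networks via Graph Signal
    Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes parcellated resting-state BOLD timeseries on
    individual structural connectomes using the graph Fourier transform,
    splitting each areal signal into a structurally coupled (low graph
    frequency) and decoupled (high graph frequency) component, and
    quantifies per-area coupling (S_C) and decoupling (S_D) as temporal
    norms of the filtered signals.  Downstream inference includes behavior
    partial least squares (PLS) of areal (de)coupling against age with
    permutation tests, bootstrap ratios and network-level summaries, and
    mass-univariate quadratic age regression with Benjamini-Hochberg FDR
    control.  A weighted block-model cohort simulator with planted
    age-by-group coupling effects makes the full pipeline testable
    end-to-end without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
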