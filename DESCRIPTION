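Package: chemfuse
Title: Two-Block Spectroscopic Fingerprinting and Mid-Level Data Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for geographic-origin authentication of plant extracts from
    1H NMR and excitation-emission matrix (EEM) fluorescence fingerprints.
    Implements NMR spectral bucketing with solvent-region exclusion and
    total-intensity normalization, EEM scatter removal with shape-preserving
    interpolation, non-negative PARAFAC with the core consistency diagnostic
    (CORCONDIA), one-class SIMCA with normalized Q/T2 reduced distances and a
    tuned acceptance threshold, duplex calibration/test splitting, and
    ComDim/CCSWA multiblock decomposition feeding a score-distance /
    orthogonal-distance one-class classifier for mid-level data fusion. A
    synthetic-data module generates class-structured spectra and trilinear EEM
    cubes with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
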