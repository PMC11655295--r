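Package: hicstain
Title: Color Chromatin Contact Maps by 1D Genomic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates 1D genomic signals (ChIP-seq coverage, compartment
    eigenvectors, peak calls, chromHMM segmentations) directly into 2D
    chromatin contact maps. A scaled 1D signal s is lifted to a signal
    matrix m[i,j] = s[i] * s[j], weighted by the unit-scaled contact map,
    and converted to per-pixel 8-bit alpha; multiple tracks are combined by
    alpha-weighted linear color interpolation. Includes observed/expected
    distance normalization, a signed two-color eigenvector mode, a
    chromHMM state-color mode, per-mark overlap quantification with
    rank-sum tests, a synthetic scene generator for testing, and PNG/SVG
    export with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
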