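Package: rna2array
Title: Design, Synthesis Planning and Quantification for Enzymatically
    Converted RNA Microarrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational companion to the enzymatic conversion of DNA
    microarrays to RNA microarrays via photocrosslinked 2'-O-methyl RNA
    primers and T7 RNA polymerase extension. Designs convertible template
    libraries (universal primer-complement block, dT surface linkers,
    untranscribable controls, linker/permutation variant series, dA-walk
    templates), encodes RGB bitmaps as arrays of per-channel template
    truncations, plans maskless photolithographic synthesis (cycle
    schedules and per-cycle micromirror masks with a replay verifier),
    simulates hybridization scans, and quantifies scans (replicate
    aggregation, control subtraction, max-normalization, conversion
    efficiency, degradation residuals, positional incorporation profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
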