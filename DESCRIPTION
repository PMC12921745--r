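Package: ptmfdr
Title: Group-Specific Transferred FDR for Sequential PTM Closed Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical post-processing for sequential closed-search
    identification of post-translational modifications (PTMs) in shotgun
    proteomics. Implements group-specific (PTM-specific) false discovery
    rate estimation by the transferred-FDR method with a spline-linear
    model of the modified-decoy proportion, Poisson error-propagation
    filtering of unstable high-rank thresholds, and inflection-point
    anchoring of spline knots on the decoy/target ratio. Also provides a
    reduced PTM search-space database builder (annotated proteins plus
    random entrapment sequences and reversed decoys), a synthetic
    peptide-spectrum-match simulator with ground-truth labels for FDR
    calibration studies, and a pipeline that merges per-PTM search
    results, applies the FDR filter, and reports modification site and
    protein coverage tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Biostrings,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
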