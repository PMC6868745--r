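Package: reosig
Title: Rank-Based Gene-Pair Signatures for Single-Sample Tumor Subtyping
Version: 0.1.0
Authors@R:
    person("reosig", "developers", email = "reosig@example.org", role = c("aut", "cre"))
Description: Discovery and application of qualitative, within-sample
    relative-expression-ordering (REO) gene-pair signatures that classify
    individual tumor samples by histological subtype. Implements the full
    discovery pipeline for non-small cell lung cancer subtyping -- calling
    subtype-opposite genes against normal controls, screening oriented gene
    pairs with a one-sided Fisher exact test under false discovery rate
    control, and seed-based forward selection with strict-majority voting --
    together with the frozen two-gene rule (SCC if KRT5 > AGR2, otherwise
    ADC), supporting validation statistics (proliferation scores, marker
    contrasts, immunohistochemistry staining indices), a synthetic-data
    generator with planted subtype-opposite structure, and a command-line
    interface. Classification uses only the ordering of expression values
    within one sample, so calls are invariant to any monotone per-sample
    transform and need no cross-sample normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
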