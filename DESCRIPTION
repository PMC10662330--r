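Package: orthoscale
Title: Cross-Species Expression Comparison via Conserved-Ortholog Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares bulk RNA-seq expression between two related species
    sharing no common reference. Builds reciprocal-best-hit ortholog pairs
    from tabular alignment output, derives per-sample scaling factors from
    the median expression of a high-identity conserved ortholog core,
    scores each ortholog pair for differential expression with an exact
    conditional binomial test whose null proportion is calibrated on the
    conserved genes, and screens coding-sequence pairs for selection with
    the Nei-Gojobori (1986) Ka/Ks estimator and a Fisher exact test filter.
    Includes a negative-binomial two-species simulator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
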