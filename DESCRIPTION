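Package: grnsign
Title: Sign-Consistency Assessment of Gene Regulatory Networks Against
    Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess how well a signed, directed gene regulatory
    network (activation/repression edges between transcription factors and
    their targets) explains a multi-dataset gene expression compendium.
    Expression contrasts between reference and case samples are discretized
    into up/down/unchanged labels with a quantile-calibrated threshold, and a
    conservative sign-consistency model counts definite contradictions
    between labels and edge roles. Observed inconsistency loads are compared
    against two empirical null models (expression-profile shuffling and
    degree-preserving network rewiring), and regulator-target expression
    correlations are summarized by interaction role. A linear-Gaussian
    steady-state simulator generates signed networks and GRN-driven
    expression compendia with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
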