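Package: qtlactivity
Title: Treatment-Dependent QTL Activity Patterns in Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-marker likelihood-ratio-statistic (LRS) mapping of strain-mean
    traits in recombinant inbred (RI) mouse panels, with permutation-based false
    discovery rates for transcriptome-wide scans and genome-wide empirical p-values
    for behavioral traits. Significant expression QTLs are classified by gene-marker
    geometry (cis, syntenic trans, non-syntenic trans) and by their QTL activity
    pattern: the binary vector recording in which of four treatment conditions
    (saline control, ethanol, restraint, ethanol plus restraint) the association
    exceeds the panel significance threshold. Cross-population conservation of
    eQTLs is assessed by nearest-marker matching between panels and summarized as
    a 50-Mb sliding-window conservation-ratio track, and candidate genes for
    behavioral QTLs are prioritized by matching and correlating activity patterns.
    Includes a synthetic two-panel study generator with planted, treatment-dependent
    genetic effects and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
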