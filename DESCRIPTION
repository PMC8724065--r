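Package: onest
Title: Observers Needed to Evaluate Subjective Tests (ONEST)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies interobserver reproducibility of categorical scoring
    with ONEST (Observers Needed to Evaluate Subjective Tests): overall
    percent agreement (OPA) curves across permutations of observers, sampled
    and exhaustive envelopes, bandwidth and plateau summaries, intraclass
    correlation ICC(2,1) with confidence intervals and reliability grading,
    and Kruskal-Wallis comparison of minimum OPA curves. Ships the breast
    immunohistochemistry categorization schemes commonly applied to ER, PR
    and Ki67 scoring (1%/10% cut-offs, St Gallen Ki67 cut-offs, Allred quick
    score groups) and a synthetic rater-panel generator for method evaluation
    when real multi-rater data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
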