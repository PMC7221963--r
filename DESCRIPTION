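Package: teaphenolics
Title: MS/MS Annotation of Green Tea Polyphenols and Antioxidant Activity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling green tea polyphenols from negative-mode
    high-resolution MS/MS peak lists and for scoring antioxidant activity.
    Provides exact monoisotopic mass and ring-double-bond arithmetic over
    elemental formulas, a diagnostic neutral-loss rule engine that calls
    compound classes (catechins, proanthocyanidins, flavonol O-glycosides and
    their acylated derivatives, flavone C-glycosides, phenolic acids,
    saccharides), aglycone identification with 3-O-glycosylation evidence from
    radical-aglycone dominance, and a transcribed compound library for
    spectrum matching. Assay mathematics cover percent inhibition, ID50 by
    log-linear interpolation or four-parameter logistic fit, Trolox-equivalent
    antioxidant capacity (TEAC), ORAC curve normalization and area under the
    curve, and Trolox-equivalent slopes. Activity profiles are summarized by
    standard scores, the relative antioxidant capacity index (RACI), and
    correlation-distance average-linkage clustering. A deterministic
    synthetic-data generator emulates QqTOF spectra with ppm-scale mass error
    and Hill-shaped dose-response curves so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
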