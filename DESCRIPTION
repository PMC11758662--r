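Package: swimcoord
Title: Inter-Limb Coordination Analysis of Horse Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies inter-limb coordination of horses swimming in a pool
    from per-limb propulsion/return event timings. Normalizes raw event times
    into percent-of-cycle coordination diagrams, computes duty factors,
    propulsion-start delays and signed overlaps (sliding as negative overlap),
    and the composite lateral and diagonal ratios alpha and beta. Classifies
    laps into four coordination categories with a two-step k-means threshold
    classifier, evaluates predicted categories against expert strategy labels
    (confusion matrix, precision/recall/F1, permutation tests), and ships a
    synthetic lap generator with bundled reference category profiles for
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
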