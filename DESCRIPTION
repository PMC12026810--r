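Package: camAAI
Title: Vessel-Network Morphometrics and the Angiogenic Activity Index for
    the Chick Chorioallantoic Membrane Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification of angiogenesis in the chick chorioallantoic
    membrane (CAM) assay from vectorized vessel networks or pre-tabulated
    per-embryo metrics.  Provides skeleton-graph morphometrics (junction
    counts, segment lengths, vessel density, branch hierarchy by
    generation order), day-0-normalized fold changes, Kaplan-Meier
    survival with the Mantel-Cox log-rank test, the per-parameter and
    final angiogenic activity index (AAI), scratch wound-healing and
    delta-CT expression arithmetic for the accompanying in vitro
    readouts, and a synthetic CAM-cohort simulator with closed-form
    expected outcomes for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
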