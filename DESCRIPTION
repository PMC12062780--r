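Package: ciuscreen
Title: Collision-Induced Unfolding Screening of Kinase Inhibitor Binding Mode
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying kinase inhibitors as type I
    ('DFG in') or type II ('DFG out') binders from native ESI-IMS-MS
    collision-induced unfolding (CIU) experiments on the FGFR1 kinase
    domain. Provides native mass-spectrum processing (peak picking,
    charge-state assignment, mass determination, bound-fraction
    quantitation), arrival-time-distribution processing with a
    two-conformer Gaussian model and the unfolded-population statistic,
    a calibrated two-voltage nearest-class-mean classifier, and the three
    binding-affinity models used alongside the screen (one-site ITC,
    1:1 steady-state SPR, MST Hill n = 1). Because raw instrument data
    for such screens are rarely deposited, a seeded forward-model
    simulator generates native spectra, CIU arrival-time distributions
    with ground truth, and titration datasets with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
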