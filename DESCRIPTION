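Package: vestgait
Title: Dynamic-Stability Gait Analysis for Vestibulopathy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes dynamic-stability, spatial, temporal and kinematic gait
    parameters (margin of stability via the extrapolated centre of mass,
    whole-body angular momentum, head anchoring indices, GaitSD, zone-based
    centre-of-mass and foot deviation scores, spatiotemporal measures) from
    3-D marker trajectories of walking trials, and evaluates their
    discriminant and convergent validity across bilateral-vestibulopathy,
    unilateral-vestibulopathy and control groups using Kruskal-Wallis tests
    with Dunn-Holm post-hocs, Pearson correlations with the Dizziness
    Handicap Inventory, and a relevance synthesis that yields a short-form
    functional gait assessment. Includes a kinematic synthetic-walker module
    that generates full marker-set motion-capture cohorts with ground-truth
    sidecars so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
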