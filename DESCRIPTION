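Package: pvscable
Title: Heterogeneous Purkinje-Ventricular Cable Simulation and Repolarization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates electrical propagation in a one-dimensional strand of the
    Purkinje-ventricular system (Purkinje, endocardial, midmyocardial and
    epicardial layers coupled by gap junctions) with a built-in Hodgkin-Huxley
    type ventricular membrane model supporting graded block of the rapid
    delayed-rectifier potassium current (IKr) and the L-type calcium current
    (ICaL). Provides conduction-velocity and junctional-delay calibration,
    pseudo-ECG computation with QT and Tpeak-end extraction and T-wave
    morphology tagging, detection and spatial classification of early
    afterdepolarizations (EADs), alternans detection, and an orchestrated
    parameter-space sweep over channel-block levels and pacing cycle lengths
    with map rendering and CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
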