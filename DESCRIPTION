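Package: mertopo
Title: Topology of Subthalamic Microelectrode Recordings Under Graded Propofol Sedation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative microelectrode recordings (MER)
    acquired during subthalamic deep brain stimulation surgery under local or
    propofol-based general anesthesia. Extracts single-unit features (firing rate,
    burst index from a two-component Gaussian mixture on log interspike intervals,
    robust coefficient of variation), profiles normalized root-mean-square (NRMS)
    background activity along trajectories, quantifies sedation depth from frontal
    EEG via the 95% spectral edge frequency (SEF95), maps recording sites and final
    electrodes against an ellipsoid atlas of the subthalamic nucleus and substantia
    nigra with a configurable stimulation sweetspot, and provides the group-level
    statistical layer (cluster-based permutation testing across aligned depths,
    ANOVA/MANOVA with eta-squared effect sizes, rank correlations, multiple-testing
    control, and post hoc power approximations). A seeded synthetic-cohort generator
    emulates the statistical structure of such surgical cohorts so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
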