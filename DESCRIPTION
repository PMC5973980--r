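Package: eusplan
Title: Simulation-Based Planning of Endoscopic Ultrasound Views for
    Registration Initialisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans patient-specific endoscopic ultrasound (EUS) sector views
    that maximise the accuracy and robustness of landmark-to-structure rigid
    registration between intra-procedure ultrasound and a pre-procedure
    labelled 3D volume. Organ surfaces and vessel/duct centrelines are
    extracted from an integer-labelled volume, physically plausible sector
    planes are sampled on the transducer contact surface (stomach or
    duodenum), anatomical landmarks are extracted automatically from each
    plane, and a Monte-Carlo simulation of landmark localisation error yields
    a target registration error (TRE) distribution per candidate plane or
    plane pair. Planes are ranked by the 90th percentile of simulated TREs
    and the selected optimum is re-estimated on independent simulations. A
    built-in synthetic abdominal phantom generator makes the whole pipeline
    runnable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
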