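Package: punctforce
Title: Proxy-Based Haptic Force Rendering for Virtual Needle Insertion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the axial forces felt at the handle of a puncture
    needle advanced along straight trajectories through CT-derived virtual
    patients, as used in percutaneous transhepatic cholangiography (PTC/PTCD)
    training simulators. A four-phase proxy/spring model (pre-puncture
    non-linear spring, post-puncture release, viscous pass, transition)
    renders cut, friction and stiffness forces from a per-tissue haptic
    parameter table. Tissue at the needle tip is taken from explicit
    segmentation masks where available and otherwise classified from CT
    intensity by a position-state-dependent threshold transfer function.
    The package also plans skin-to-bile-duct insertion trajectories under
    hard and soft constraints, generates layered synthetic phantom volumes
    with controlled segmentation discrepancies, and evaluates force-signal
    agreement with RMSE, maximum absolute error, percent-identical forces,
    per-structure border-lag distances and Weber-fraction just-noticeable
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
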