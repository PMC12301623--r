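Package: psoct
Title: Catheter-Based Polarization-Sensitive OCT Birefringence Mapping and
    MRI Co-Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for catheter-based
    polarization-sensitive optical coherence tomography (PS-OCT) of brain
    tissue along deep-brain-stimulation-style insertion trajectories.
    Provides Poincare-sphere rotation algebra for retarders, a physics-based
    synthetic pullback simulator (layered grey/white-matter phantom, rotating
    catheter with a birefringent sheath, speckle and detector noise, matched
    T1-like MRI rendering), depth-resolved local retardance and absolute
    optic-axis reconstruction via cumulative rotation retrieval, transmission
    compensation, layer peeling and guide-star sheath correction, unrolled
    en-face carpet views co-registered with unfolded MRI regions of interest,
    and binary white/grey-matter tissue barcodes from 1-D profiles via
    two-means clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
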