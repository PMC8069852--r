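Package: nmmfc
Title: Neural Mass Model Ground Truth for Functional Connectivity Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of rhythm-specific cortical regions with a
    four-population neural mass model (pyramidal cells, excitatory
    interneurons, slow and fast GABAergic interneurons), each region tuned to
    an intrinsic theta, alpha, beta or gamma rhythm, and uses the simulated
    pyramidal membrane potentials as ground truth to benchmark eight bivariate
    functional-connectivity estimators (correlation, delayed correlation,
    coherence, lagged coherence, phase synchronization, temporal and spectral
    Granger causality, transfer entropy). Provides random-network ROC/AUC and
    precision-recall benchmarks, connection-strength sweeps, input
    (working-point) sweeps and spectral connectivity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
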