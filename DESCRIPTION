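Package: septostrain
Title: Septal Strain Discoordination Analysis for Exercise Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mechanical discoordination of the inter-ventricular
    septum from speckle-tracking echocardiography. Provides a scatterer-based
    synthetic ultrasound generator with known ground-truth deformation,
    mesh-based block-matching strain tracking with a least-squares strain
    estimator, heart-rate-dependent scaling of valve timing, decomposition of
    systolic strain into shortening and rebound-stretch components (systolic
    rebound stretch, systolic shortening and the septal discoordination
    index), and the agreement statistics used in test-retest and observer
    reproducibility studies (Bland-Altman, two-way absolute-agreement ICC,
    Cohen's kappa, paired t-tests, feasibility tallies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2
Config/testthat/edition: 3
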