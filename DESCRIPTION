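Package: strokemap
Title: Lesion-Symptom, Structural-Disconnection and Lesion-Network Mapping
    for Post-Stroke Depressive Symptoms
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for relating focal brain lesions to
    continuous symptom scores (HADS-D depressive symptoms after stroke)
    through four complementary inference routes: multivariate support
    vector regression lesion-symptom mapping (SVR-LSM) with permutation
    voxel- and cluster-level family-wise-error control,
    structural-disconnection-symptom mapping (SVR-SDSM) built on
    normative tractograms, lesion network-symptom mapping (LNSM) from a
    normative resting-state connectome, and a circuit-based network
    damage score with a permutation group test. Includes a synthetic
    cohort generator with planted ground truth so every stage is
    testable without patient data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
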