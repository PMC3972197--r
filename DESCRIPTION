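Package: lesionpatterns
Title: Two-Tier Spatio-Temporal Classification of Enhancing MS Lesions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterizes multiple sclerosis disease onset from longitudinal
    gadolinium- and USPIO-enhanced lesion masks. Tier one represents each
    lesion by rotation-invariant coordinate-covariance eigenvalues plus a
    hollowness index distinguishing ring from focal enhancement, matches
    lesions across time points and contrast agents by spatial overlap, and
    clusters lesion trajectories with self-tuning spectral clustering; the
    cluster count is estimated by decision fusion of four validity indices
    (Dunn, Calinski-Harabasz, gap statistic, Laplacian eigengap). Tier two
    summarizes patients by cluster cardinalities and regresses future chronic
    hypointense lesion load on them with a no-intercept least-squares model
    evaluated by leave-one-out R-squared. Includes permutation and
    randomization tests of cluster separation and a synthetic cohort
    generator emulating the study design for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
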