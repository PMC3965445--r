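Package: mretools
Title: Simulation and Reconstruction of Mouse Brain Magnetic Resonance
    Elastography with Longitudinal Statistics and Stereology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in silico magnetic resonance elastography (MRE) of the
    mouse brain. Simulates harmonic shear-wave propagation through a 2D
    viscoelastic phantom (finite-difference Helmholtz solver), encodes the
    displacement field into wrapped motion-sensitized MR phase-image series,
    and reconstructs per-pixel complex shear modulus maps by phase
    differencing, 2D phase unwrapping, temporal harmonic extraction, radial
    Butterworth band-pass filtering and algebraic Helmholtz inversion.
    Includes ROI-wise viscoelastic summaries, mixed-design (repeated-measures)
    and fully between-subjects two-way ANOVA with Bonferroni pairwise
    comparisons for longitudinal group studies, and stereological cell-count
    estimators (series scaling, double-label proportions, optical
    fractionator) with synthetic count generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
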