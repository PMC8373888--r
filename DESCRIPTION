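Package: conncoh
Title: Structural and Functional Connectome Coherence Analysis for Glioma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-level structural (streamline edge-weight and
    fractional anisotropy) and functional (Fisher-z correlation) brain
    connectivity matrices from parcellated derivatives, reduces them to
    lesion-relabelled hemispheric compartment means, and runs group
    comparisons (one-way MANOVA with Pillai's trace, univariate follow-ups,
    pooled-error Bonferroni post-hocs) together with age-controlled partial
    correlation profiles quantifying intramodal and intermodal connectomic
    coherence. Includes a synthetic multimodal cohort generator with
    plantable group effects and latent coherence factors for power,
    calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
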