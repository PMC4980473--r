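Package: icafluct
Title: Group ICA of Block-Design fMRI with Fluctuation and Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Temporal-concatenation group independent component analysis of
    multi-subject block-design fMRI with bootstrap stability selection,
    spectral artifact screening by low-frequency power ratio, two
    task-relatedness tests on back-projected component time courses, a
    Fano-factor-style within-block fluctuation index with its task
    comparison and self-report association, block-wise residual-correlation
    coupling labels between components, and a reference voxelwise GLM. A
    synthetic cohort generator with known spatial maps, condition-dependent
    baselines and fluctuation, signed latent couplings, and dedicated
    artifact components makes the whole pipeline testable end to end
    without any real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
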