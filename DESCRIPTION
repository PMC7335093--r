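Package: fiberfilter
Title: Discriminative Fiber Filtering for Brain-Stimulation Network Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate fiber filtering for deep brain stimulation (DBS)
    connectivity analysis. Given a tractogram in world millimetre coordinates
    and a cohort of binary stimulation volumes (volumes of tissue activated)
    with clinical outcomes, the package scores every streamline with a
    two-sample t-statistic contrasting outcomes of connected versus
    unconnected stimulations, aggregates fiber scores under each stimulation
    volume with amplitude normalisation, attaches permutation p-values to
    score-outcome correlations, cross-predicts outcomes between cohorts, and
    scores literature-defined stereotactic targets against a fitted tract
    model. A synthetic-data generator plants a coherent fiber bundle in
    incoherent background and simulates stimulation cohorts whose outcomes
    are a noisy linear function of bundle overlap, so the whole pipeline is
    testable without patient data. Readers and writers for TRK, TCK, NIfTI
    masks and cohort tables are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    methods,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
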