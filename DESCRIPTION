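Package: neuroXmap
Title: Imaging Transcriptomics and Brain-Immune Association Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking resting-state fMRI amplitude maps to regional
    transcriptomes and peripheral immune profiles. Computes the amplitude of
    low-frequency fluctuations (ALFF) from voxel time series, voxel-wise
    correlation and two-sample statistic maps with Gaussian-random-field
    cluster-level correction and a permutation alternative, atlas parcel
    extraction, donor-microarray regional expression matrices (probe
    filtering, differential-stability probe selection, robust sigmoid
    normalization), gene-wise spatial correlation with FDR control,
    single-sample gene-set enrichment (ssGSEA) and hypergeometric
    over-representation scoring, immune-signature infiltration scoring,
    empirical-Bayes moderated-t differential expression for RNA-seq counts,
    and MCODE dense-module detection on interaction graphs. A synthetic-data
    module generates every input with planted ground truth so the complete
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    igraph,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
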