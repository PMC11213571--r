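Package: IntrinsicEphys
Title: Intrinsic Electrophysiology Feature Extraction and Neuron-Type
    Classification from Current-Clamp Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts intrinsic electrophysiological properties (action
    potential and afterhyperpolarization landmarks, rheobase, input
    resistance, membrane time constant, capacitance, sag, spike delay,
    frequency-current slope) from whole-cell current-clamp sweep bundles,
    classifies neurons into putative cell types by standardized PCA followed
    by Ward hierarchical clustering, and computes soma-contour and
    dendritic-tree morphometrics from SWC reconstructions. Ships a seeded
    synthetic-data module (adaptive leaky integrate-and-fire simulator with
    stylized action-potential templates, soma-polygon and dendritic-tree
    generators) providing ground truth for every estimator, plus a
    group-comparison layer with a Kolmogorov-Smirnov normality gate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
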