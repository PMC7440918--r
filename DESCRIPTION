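Package: vtaSst
Title: Electrophysiological Subtyping of Midbrain Somatostatin Neurons
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for identifying somatostatin-neuron
    subtypes in the mouse ventral tegmental area from whole-cell
    current-clamp recordings. Extracts 25 passive and active membrane
    features from current-step sweep ladders, selects a principal-component
    order by cross-validated BIC, clusters cells with Gaussian mixture
    models, analyses optogenetic circuit-mapping grids (optical footprints,
    inhibitory input maps, Nernst reversal potentials), performs Patch-seq
    quality control with PC1-based count normalization and bootstrap
    mapping to a reference single-cell dataset, and scales anatomical
    section counts to whole-structure estimates. A synthetic-data module
    generates membrane-potential traces, photostimulation sessions and
    Patch-seq count matrices with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mclust,
    minpack.lm,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'sweep-io.R'
    'spike-features.R'
    'clustering.R'
    'optomap.R'
    'patchseq.R'
    'anatomy.R'
    'synthetic.R'
    'report.R'
    'pipeline.R'
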