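Package: peelfusion
Title: Multi-Block Chemometric Fusion and Texture Profiling of Citrus Peel Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative chemometric evaluation of citrus fruit
    peels from heterogeneous analytical blocks: grayscale image texture
    profiling (first-order, co-occurrence and run-length statistics), ATR-FTIR
    band-intensity tables, physicochemical and spectrophotometric assay panels.
    Provides a SummarizedExperiment-based multi-block container with
    auto-scaling and horizontal fusion, linear discriminant analysis with
    stratified cross-validation, non-parametric class comparison with compact
    letter displays, and thresholded Pearson correlation networks. A synthetic
    replicate generator parameterized from published class means and standard
    deviations makes every stage testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'blocks.R'
    'datagen.R'
    'texture.R'
    'spectra.R'
    'classcomp.R'
    'fusion.R'
    'network.R'
    'pipeline.R'
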