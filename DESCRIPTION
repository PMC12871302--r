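Package: axonsynkit
Title: Quantifying Axonal Transport, Presynaptic Sites, Network Activity and
    Expression in Human iPSC-Derived Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification
    procedures used to phenotype pathogenic KIF1A variants in human
    iPSC-derived (NGN2) neurons: kymograph tracing and synaptic-vesicle-
    precursor transport metrics (direction classification, flux, top-five
    "maximum velocity", motile intensity), stable SVP+ site detection and
    microtubule plus-end comet association, multi-electrode-array spike,
    burst and network-burst analysis, synapse apposition counting and
    density, delta-delta-Ct relative expression, and replicate-aware
    (SuperPlot) summarization. A synthetic-data generator with
    genotype-dependent presets produces ground-truth inputs for every
    stage, so each detector can be scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    EBImage,
    igraph,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
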