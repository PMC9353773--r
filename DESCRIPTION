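Package: metsite
Title: Metastasis-Site Prediction and Interpretation from Gene Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-phase deep-learning workflow for predicting whether a tumour
    expression profile is primary or has metastasised to bone, brain, lung or
    liver. Phase one trains an autoencoder per metastasis site, ranks genes by
    DeepLIFT contribution to the bottleneck layer, and searches for the
    smallest top-ranked gene panel that maximises binary AUC. Phase two trains
    a five-class dense classifier on the merged panel and interprets it at the
    neuron level: class-conditional relevance propagation, t-test selection of
    essential neurons, back-attribution to essential input genes, and local
    Fisher-exact over-representation analysis against GMT gene-set files. The
    dense-network engine (Adam, L2, inverted dropout, early stopping) and the
    DeepLIFT rescale-rule attribution are implemented in full so that every
    neuron is inspectable. A synthetic-cohort generator with planted
    site-specific signatures makes the whole pipeline testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
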