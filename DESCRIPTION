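Package: pcsfCompare
Title: Comparative Proteomic Network Analysis with Prize-Collecting Steiner Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression, enrichment, human-genetics integration
    and comparative network analysis for multiplexed (TMT) proteomics of two
    disease conditions. Dysregulated proteins are mapped onto a confidence
    weighted protein-protein interactome with a prize-collecting Steiner
    forest solver, stabilized by jittered re-solving and a degree-preserving
    specificity null, smoothed by personalized PageRank, and clustered by
    Louvain community detection on cosine affinities to separate condition
    specific from shared modules. Includes a synthetic-data generator that
    plants connected dysregulation modules with known condition patterns for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
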