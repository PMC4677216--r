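Package: balcornet
Title: Correlation Network Analysis of Paired miRNA and mRNA Expression in
    Bronchoalveolar Lavage Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for paired microRNA and mRNA qPCR expression
    profiles from bronchoalveolar lavage (BAL) cells, built around a sarcoidosis
    study design with progressing and regressing disease subgroups and healthy
    controls. Provides quantification-cycle (Cq) calling from raw amplification
    curves by the second-derivative-maximum method, calibrator-relative
    reference-normalised expression, nonparametric differential expression
    (Kruskal-Wallis and Mann-Whitney with exact small-sample nulls),
    significance-filtered Spearman miRNA-mRNA-transcription-factor correlation
    networks with a chord-diagram weight transform and Circos tableviewer
    export, Kohonen self-organizing-map clustering of patient profiles, and
    nearest-neighbour reduction of the weighted coexpression graph. A Gaussian
    copula synthetic-cohort generator with planted group shifts and planted
    rank correlations makes every stage testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
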