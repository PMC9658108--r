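Package: comorbnet
Title: Comorbidity Pattern Discovery in Stratified Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sex- and age-stratified comorbidity networks from coded
    diagnosis records. Diagnoses are reduced to chronic disease categories via
    user-supplied lookup tables, pairwise associations are measured by
    maximum-likelihood tetrachoric correlation (with a purpose-built bivariate
    normal orthant-probability core and a likelihood-ratio test of zero
    correlation), significant positive correlations become weighted network
    edges, and disease patterns are extracted by Louvain modularity
    optimization. Includes a latent-Gaussian synthetic cohort generator with
    planted block-correlation structure so the whole chain can be validated
    against known ground truth, plus GraphML/GEXF export for network
    visualization tools.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
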