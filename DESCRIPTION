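Package: eqtlgrowth
Title: Integrating eQTL and Growth QTL Maps in a Yeast Segregant Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for connecting the genetics of gene expression to the
    genetics of growth in a panel of haploid yeast segregants. Computes
    expression-growth genetic correlations with Storey q-values, decomposes
    them into local-eQTL, trans-eQTL and trans-eQTL hotspot sources, estimates
    marker-set heritability by single-component REML on genetic relatedness
    matrices, tests pleiotropy versus linkage with a bivariate two-QTL scan
    and parametric bootstrap, quantifies mediation of hotspot effects through
    individual transcripts with bootstrap inference, and performs signed
    gene-set enrichment with trait clustering. Includes a synthetic segregant
    panel generator with full ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
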