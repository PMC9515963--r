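Package: stomaflora
Title: Stoma-Associated Fecal Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of 16S amplicon fecal-microbiome cohorts
    contrasting patients with and without a stoma: consort-style sample
    exclusion and rarefaction, Gram-stain and oxygen-requirement trait
    propagation over taxonomic ranks, alpha diversity (observed features,
    Shannon, Faith's phylogenetic diversity) at ASV, gene-family and pathway
    level, UniFrac/PCoA/PERMANOVA beta diversity, Dirichlet Monte-Carlo
    centred log-ratio differential abundance with standardized effect sizes,
    preranked gene-set enrichment over KEGG orthology effect sizes, and
    Common/Uncommon/Rare presence attribution of diversity shifts. Includes a
    Dirichlet-multinomial synthetic community generator that plants the
    contrasts the analysis is designed to detect, so every stage is testable
    without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vegan,
    picante
Config/testthat/edition: 3
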