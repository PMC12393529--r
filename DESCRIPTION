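Package: symbiopan
Title: Phylosymbiosis Assessment from Bacterial Pangenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess phylosymbiosis between animal hosts and bacterial
    symbionts from genome-scale data: pangenome core/accessory/unique
    partitioning with gene accumulation curves and openness (Heaps' law),
    ANI-based phylogroup delineation, accessory-genome similarity networks
    with categorical assortativity, Procrustes-based cophylogeny testing
    (PACo) with an explicit signal/congruence classification framework,
    information-based generalized Robinson-Foulds tree comparison,
    pangenome-wide association of gene presence with lifestyle (Fisher's
    exact test with Bonferroni control), and read-recruitment RPKM profile
    concordance (Bray-Curtis, UPGMA). Includes seeded synthetic-data
    generators (cophylogenies with tunable host switching, structured
    pangenome matrices, block ANI matrices, read counts) so the entire
    pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
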