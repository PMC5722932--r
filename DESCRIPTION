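Package: camps
Title: Microsynteny Detection and Evolution of Conserved Ancestral
    Microsyntenic Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects fine-scale syntenic gene pairs (microsynteny) from
    genome annotations, reconstructs the evolutionary history of such
    clusters on a species phylogeny under Dollo parsimony, counts cluster
    duplications by gene-tree/species-tree reconciliation, classifies
    cluster disruptions, and issues CAMP (conserved ancestral microsyntenic
    pair) calls from shared enhancer blocks via signed TSS distances.
    Includes the expression-side call coding used alongside such analyses
    (0/up/down regulation calls, delta-delta-Ct fold changes, delta-Ct
    regression) and a forward simulator of gene-order evolution (cluster
    gain, en-bloc duplication, gene loss, inversion, translocation) that
    provides ground truth for end-to-end recovery tests. Ships the human
    PDI/RhoGDI pair coordinates, their enhancer blocks, and the eight-species
    presence/absence pattern as built-in fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
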