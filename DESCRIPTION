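Package: fcptools
Title: Discovery, Classification and Binding-Site Annotation of
    Fucoxanthin Chlorophyll a/c-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for annotating the light-harvesting
    antenna (FCP/LHC) protein repertoire of a microalgal proteome.
    Discovers fucoxanthin chlorophyll a/c-binding protein (FCP) candidates
    by Smith-Waterman local alignment with Karlin-Altschul E-value
    statistics, assigns them to the Lhcf/Lhcr/Lhcx families by best-hit
    homology against labeled diatom reference panels with cladogram-based
    reconciliation of ambiguous cases, builds neighbor-joining cladograms
    under the 20-state Jukes-Cantor distance with bootstrap supports,
    assigns Lhcf sequences to lineage-restricted groups A-D, and transfers
    crystallographically characterized chlorophyll and fucoxanthin binding
    residues from a reference species onto target Lhcf proteins through
    multiple-alignment columns, reporting per-site presence percentages.
    Includes a sequence-family simulator (Yule trees, uniform 20-state
    substitution, implanted binding sites) providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
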