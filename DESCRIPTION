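Package: SRNaseEvol
Title: Molecular Evolution of S-RNase Alleles Under Gametophytic
    Self-Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the molecular evolution of S-RNase
    coding sequences under RNase-based gametophytic self-incompatibility.
    Implements pairwise synonymous/non-synonymous divergence (Nei-Gojobori
    counting with Jukes-Cantor correction), dual-method calling of
    positively selected amino acid sites, a MaxChi-style permutation scan
    for gene-conversion tracts with consolidation into independent events
    and an events-per-synonymous-mutation ratio, single-linkage clustering
    of sequences into allelic specificities with genus sharing and lineage
    ages, the new-specificity rate and its Poisson divergence threshold,
    population-genetic rate arithmetic (theta = 4*Ne*mu), parsimony
    networks of replacement changes with conservative/non-conservative
    classification, Shrake-Rupley accessible surface area of selected
    sites and lysine conservation profiles, and a Gillespie codon
    simulator with omega site classes and gene conversion for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
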