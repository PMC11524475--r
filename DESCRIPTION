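Package: nrcdiverge
Title: Clade Divergence Profiling of Helper NLR Dimerization Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how protein-protein interaction interfaces
    diverge between phylogenetic clades of a protein family, motivated by
    the NRC clade of solanaceous helper NLR immune receptors. The package
    curates sequence sets (length filters, exact deduplication, tree-guided
    clade assignment), trims gappy alignment columns, maps
    reference-numbered interface stretches onto an alignment, profiles
    per-column Shannon entropy within any sequence subset, and identifies
    clade-unique residues with the relative amino-acid-ratio statistic
    (frequency and fold-change cutoffs with explicit infinite/NA rules).
    A structural module extracts dimerization interfaces from two-protomer
    coordinates: inter-chain contact residues at a distance cutoff, their
    grouping into named stretches by partner-domain class and contiguity,
    and buried surface area via a deterministic Shrake-Rupley solvent
    accessible surface area calculation. A synthetic-data module generates
    clade-structured families with planted clade-diagnostic polymorphisms
    and toy two-chain structures with known contacts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
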