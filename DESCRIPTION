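Package: lcsequon
Title: N-Glycosylation Sequon Analysis for Antibody Light Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises N-glycosylation sequons (NxS/T and
    the cysteine variant NxC) in antibody light-chain variable domains.
    Transfers IMGT unique numbering from assigned germline V/J genes to
    query sequences by pairwise alignment, annotates sequon position,
    region, sequence context and progenitor status, quantifies somatic
    mutation load against the germline, computes group-level enrichment
    statistics (odds ratios with Wald intervals, logistic-regression
    estimates, Benjamini-Hochberg false discovery rates, Wilcoxon rank-sum
    comparisons, positional Pearson correlations and residue-frequency logo
    matrices), and classifies residue solvent exposure on native and
    amyloid-fibril structures via Shrake-Rupley solvent-accessible surface
    area. Includes a seeded synthetic repertoire and toy-structure
    generator so that the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
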