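Package: gcgevo
Title: Comparative Evolution of Proglucagon and Its Receptor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the mammalian proglucagon gene
    (Gcg) and the receptors for its derived peptides (Gcgr, Glp1r, Glp2r):
    reference-anchored variability statistics for proglucagon-derived peptide
    regions, prohormone convertase processing-site integrity checks, genomic
    neighborhood (synteny) conservation classification, Nei-Gojobori dN/dS
    estimation with a permutation test for between-gene differences in
    selection intensity, Fitch-parsimony screening for co-substituting site
    pairs, categorization of receptor ligand- and G-protein-interacting sites,
    and seeded simulators producing every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
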