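Package: locushap
Title: Locus-Specific Haplotype Networks, Recombination Tests and Node
    Dating for Domestication Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of a single aligned gene region sampled from wild and
    domesticated accessions: haplotype collapsing, reticulate
    median-joining-style parsimony networks with an indel coded as a single
    character, population-genetic summaries (segregating sites, nucleotide
    diversity, Tajima's D, Fu and Li's D* and F*, Hudson-Kaplan minimum
    recombination events), binomial significance tests that distinguish
    recombination from repeat mutation using network homoplasy counts,
    identification of the domestication common ancestor node, and
    calibration-based node dating.  Includes a coalescent-style synthetic
    alignment generator with a machine-readable truth record for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
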