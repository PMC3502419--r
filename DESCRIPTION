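Package: degen21
Title: Serine-Aware Degeneracy Coding and 21-Amino-Acid Models for
    Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for nonsynonymous coding of in-frame protein-coding
    nucleotide alignments (degen1, degen8, degenFS2, noLRall1nt2),
    conceptual translation to 20- and 21-amino-acid alphabets that keep
    the two disjoint serine codon clusters (Ser1 = TCN, Ser2 = AGY)
    apart, construction of 20/21-state amino-acid exchangeability
    matrices by collapsing codon models and by splitting JTT serine
    rates, a serine-site classification and alignment-manipulation
    suite, compositional-heterogeneity assessment through Euclidean
    composition distances with bootstrap consensus, and a codon
    alignment simulator with controllable, possibly non-stationary,
    codon usage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
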