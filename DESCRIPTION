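Package: cpglandscape
Title: CpG Dinucleotide Landscape of Protein-Coding DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the CpG dinucleotide landscape of
    protein-coding DNA in vertebrates. Provides exact combinatorics of CpG
    sites in the standard genetic code (within-codon and codon-junction CpG
    codons, CpG-free codon repertoires, minimal synonymous escape paths,
    methylation-driven mutation effects), a normalised CpG-content statistic
    #CpG/(#CpG+#GpC) applied per gene, per genomic fragment and per terminal
    coding window, in-frame dicodon observed/expected enrichment, the
    associated nonparametric comparisons (Mann-Whitney U, Kendall tau with
    ordinary least squares, paired Wilcoxon signed-rank), a permutation test
    of genomic region overlap, and seeded synthetic generators (first-order
    Markov genomes with tunable GC fraction, strand bias and CpG depletion;
    coding-sequence sets with tunable codon usage, terminal-window depletion
    and dicodon adjustment; region fixtures with controlled overlap) so every
    stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
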