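Package: adaptscan
Title: Selection Scans and Genotype-Environment Association for Coding Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of rapid adaptive evolution in protein-coding
    genes and links them to ecological variation. Implements pairwise dN/dS by
    codon counting (Nei-Gojobori style site and difference counting with
    multiple-pathway averaging and Jukes-Cantor correction), 102-nt
    sliding-window Ka/Ks scans, McDonald-Kreitman contingency tables with
    alpha and an exact two-sided Fisher test, per-population alternate-allele
    frequencies from VCF genotypes with missingness/quality/frequency
    filtering, and a gene-level genotype-environment correlation test based on
    harmonic-mean p-value combination with percentile ranking and a
    variant-count-matched permutation null. Ships deterministic synthetic-data
    generators (diverging codon pairs, population samples with planted
    polymorphism and divergence, allele-frequency matrices with
    environment-linked genes) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
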