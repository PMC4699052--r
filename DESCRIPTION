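Package: genoSHE
Title: Somewhat-Homomorphic Encryption for Private Genome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Privacy-preserving genome analysis with two somewhat-homomorphic
    encryption schemes over cyclotomic rings: a leveled BGV-style scheme with
    modulus and key switching, and a scale-invariant YASHE-style scheme with
    word-decomposition key switching. Includes CRT plaintext-slot batching,
    integer genotype and variant encodings, homomorphic circuits for minor
    allele frequencies and the allelic chi-square statistic in case-control
    studies, Hamming and approximate edit distance circuits over VCF variant
    records, parameter-selection calculators, plaintext reference oracles, and
    a seeded synthetic-data generator for both tasks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
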