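Package: castevar
Title: Caste- and Population-Level Analysis of Transcriptome Single
    Nucleotide Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of single nucleotide variants (SNVs) called
    against a consensus reference transcriptome, as used in comparative
    studies of social insect castes and populations. Isolates biallelic SNVs
    from per-library VCFs, applies a read-depth filter, computes SNV counts
    and transition/transversion ratios, builds pyrimidine-referenced SBS-6
    and SBS-96 trinucleotide mutational catalogues, finds the longest open
    reading frame per transcript, estimates dN/dS by the Nei-Gojobori
    method with Jukes-Cantor correction (per sample and for gene subsets),
    and compares castes and populations with Kruskal-Wallis/Dunn and
    ANOVA/Tukey tests. A seeded synthetic-study generator with planted,
    calibrated selection signals makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
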