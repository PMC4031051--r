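Package: mtlextree
Title: Lexical Haplotype Tree Association Testing for Mitochondrial
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Case-control association analysis machinery for human
    mitochondrial DNA (mtDNA) genotyping-array data: ordered quality-control
    cascades for haploid genotypes, a lexical haplotype-tree association test
    with a label-permutation null (whole-tree statistic formed from the five
    largest mutually non-nested node chi-squares), haploid single-variant
    allelic association with risk-direction tallying, a case-control power
    calculation for a haploid locus, and reference-panel sequence filtering.
    Includes a synthetic-data generator that emulates haplogroup-structured
    mtDNA cohorts with planted clade effects so every stage of the pipeline
    can be exercised and calibrated without access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
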