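Package: ecosig
Title: Replication-Strand-Aware Genome and Proteome Signature Analysis for
    Bacterial Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genome/proteome signature analysis for panels of
    complete bacterial genomes, built around the ecotype differentiation of
    marine picocyanobacteria. Implements GC-skew replichore prediction and
    leading/lagging strand gene classification, relative synonymous codon
    usage (RSCU) with correspondence analysis and per-codon strand asymmetry
    chi-square tests, symmetrized dinucleotide relative-abundance genome
    signatures, amino-acid usage standardization and single-linkage
    clustering, protein physicochemical indices (GRAVY, aromaticity,
    isoelectric point, instability index) and a propensity-based secondary
    structure summary, reciprocal-best-hit ortholog filtering with
    core-proteome construction, modified Nei-Gojobori / Jukes-Cantor dN/dS
    estimation with positive-selection partitioning, synteny breakpoint
    comparison, intergenic extraction with gene-remnant filtering, and a
    fully seeded synthetic-genome generator that plants every signal the
    pipeline measures so each stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
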