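Package: mirED
Title: Detection of A-to-I Editing Hotspots in miRNA Seed Regions and
    Prediction of the Resulting Target Switching
Version: 0.99.0
Authors@R:
    person("mirED", "Maintainers", email = "maintainers@mired.example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully simulatable pipeline for calling
    adenosine-to-inosine (A-to-I) editing sites in mature microRNAs from
    small-RNA sequencing data. Reads are adapter- and quality-trimmed,
    aligned to a pre-miRNA reference with an ungapped unique-best-stratum
    mapper allowing at most one mismatch, and piled up strand-aware so the
    editing signature is always A-to-G on the miRNA strand. Candidate sites
    are tested against a sequencing-error null with an exact binomial test
    under Bonferroni control, filtered against known variants, mitochondrial
    contigs and non-pre-miRNA positions, and reduced to seed-region hotspots
    whose editing level rises across disease stages or is elevated in
    tumors. For a called seed edit the package derives the edited miRNA,
    predicts canonical seed-match target sites (8mer, 7mer-m8, 7mer-A1,
    6mer) over 3'UTRs for the canonical and edited forms, partitions genes
    into lost, gained and shared target sets, and shortlists them by fuzzy
    c-means clustering of stage-wise expression patterns. A seedable
    synthetic-data module generates the reference, annotation, variant set,
    multistage cohort reads, expression matrices and 3'UTRs needed to
    exercise and validate every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
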