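Package: neopept
Title: Neoantigen Vaccine Peptide Selection from Somatic Variants and Tumor RNA
Version: 0.1.0
Authors@R:
    person("neopept", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects and ranks candidate synthetic-long-peptide vaccine
    sequences for personalized cancer vaccines. Starting from somatic
    variants (VCF), tumor RNA read alignments (SAM/BAM), a reference
    genome (FASTA), transcript annotations (GTF) and the patient's HLA
    Class I alleles, the package assembles RNA-supported mutant coding
    sequences (phasing adjacent germline or somatic variants observed on
    the same reads), translates them into mutant protein fragments, and
    ranks 25-mer vaccine peptide windows by the product of an
    allele-specific expression score (mutation-supporting RNA read
    count) and a Class I MHC binding score (logistic-normalized
    predicted affinities of all mutant 8-11-mer epitopes across patient
    alleles). Includes manufacturability screening for solid-phase
    peptide synthesis, a pluggable peptide-MHC affinity predictor
    interface with a deterministic built-in toy predictor, and a
    deterministic generator of synthetic genomes, annotations, variants
    and spliced RNA alignments for end-to-end testing.
License: Apache License (>= 2)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
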