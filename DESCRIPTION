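Package: panmixGL
Title: Genotype-Likelihood Population Genomics for Panmixia Testing at Low Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing panmixia with low-coverage whole-genome
    sequencing data via genotype likelihoods. Provides a synthetic-data
    generator for multi-locality sampling designs with a diverged outgroup,
    low-rate introgression and a non-recombining inversion-like haplotype
    block; GATK-model genotype likelihoods with EM minor-allele-frequency
    estimation and likelihood-ratio SNP calling; iterative
    individual-allele-frequency PCA, admixture proportions by EM, and
    genotype-likelihood kinship; delta-allele-frequency contrasts with
    rolling averages and a PC-based selection scan calibrated against
    chi-square(1); inversion haplotype genotyping by kinship clustering with
    group-wise Tajima's D; site-frequency-spectrum estimation and windowed
    nucleotide diversity; and a deterministic multi-locus viability-selection
    load model quantifying the mortality implied by within-generation
    allele-frequency shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
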