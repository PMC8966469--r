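Package: triodistort
Title: Detection of Sex-Specific Transmission Distortion in Parent-Offspring Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood-based detection of sex-of-offspring-specific
    transmission distortion from parent-offspring trio genotype data. Reads
    trio pedigrees and multi-sample VCFs, applies site filters (biallelic
    SNPs, pseudoautosomal-region exclusion, Mendelian-error handling,
    informative-trio thresholds), and reduces each SNP to sex-stratified
    transmission counts. Fits three nested transmission models per SNP
    (Mendelian, uniform distortion, sex-specific distortion) with closed-form
    maximum-likelihood estimates, profile confidence intervals and
    likelihood-ratio tests; aggregates per-SNP p-values into candidate
    regions with a local-score (Lindley process) scan using Monte-Carlo
    significance thresholds; classifies signals as sex-antagonistic,
    sex-limited or sex-differential; computes intersexual Weir-Cockerham
    F_ST with matched-null region resampling and recombination-quartile
    enrichment tests. Includes trio simulators for power analysis, type-I
    calibration, recombination-free window lengths and synthetic VCF/PED
    fixture generation, plus follow-up utilities for phased haplotypes
    (allele-sharing distances, classical MDS, density clustering,
    sex-biased transmission tests, Mantel sex-structure QC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
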