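Package: popgenpipe
Title: Population-Genomic Diversity, Differentiation, Selection Scans and
    Local Ancestry for SNP Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for population-genomic analysis of
    dense diploid SNP genotypes with phased haplotypes, motivated by studies
    of structured, admixed livestock breeds. Provides PED/MAP and phased VCF
    input/output; genotype quality control (missingness, minor allele
    frequency, Hardy-Weinberg equilibrium with Bonferroni correction, linkage
    disequilibrium pruning, dataset merging with allele reconciliation);
    per-individual heterozygosity and method-of-moments inbreeding (F, Fhat3);
    pairwise identity-by-descent relatedness (PI_HAT) with greedy relatedness
    filtering; Weir-Cockerham F_ST and four-level hierarchical AMOVA with
    permutation significance; principal component analysis of standardised
    genotypes; phased-haplotype selection scans (pairwise homozygosity tract
    length H, haplotype frequency spectrum H12, variance-normalised Tajima's
    D in fixed-SNP windows) with SNP-density pruning, 0-1 scaling,
    99th-percentile peak calling, multi-statistic peak intersection and BED
    gene annotation; a posterior-thresholded window classifier for local
    ancestry of admixed haplotypes; and a seeded synthetic-data generator
    (Balding-Nichols structured populations, admixture mosaics with recorded
    truth tracts, implanted selective sweeps, neutral site-frequency-spectrum
    sites, array-style ascertainment) that exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
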