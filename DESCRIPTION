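Package: chronopop
Title: Temporal Population Genomics from Serially Collected Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for temporal population-genomic analysis of serially
    sampled (museum and modern) specimens genotyped at multilocus SNP
    panels. Implements a reproducible SNP filter chain (quality, allelic
    balance, depth, minor-allele and presence filters, indel-proximity
    pruning, one-SNP-per-locus thinning, coding/non-coding partitioning,
    depth downsampling), from-scratch diversity statistics (nucleotide
    diversity, heterozygosity, private alleles, Watterson's theta,
    Tajima's D in sliding windows, Weir-Cockerham Fst), a permutation
    subsampling framework across uneven time-point sample sizes with
    ANOVA/Tukey comparisons and demographic trend classification, and an
    immune-locus Fst-outlier scan against a non-coding neutral baseline.
    A forward Wright-Fisher simulator with an archival-DNA artifact layer
    (coverage disparities by tissue preparation, allelic dropout,
    deamination-type miscalls, missingness) generates fully synthetic
    VCF/BED/metadata bundles with known truth so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
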