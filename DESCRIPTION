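Package: pneumogwas
Title: GWAS Meta-Analysis, Finemapping, Mendelian Randomisation and
    Pharmagenic Enrichment Scoring for Case-Control Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained statistical-genetics toolkit for two-cohort
    case-control GWAS: inverse-variance-weighted fixed-effects meta-analysis
    with Cochran's Q heterogeneity testing and LD-based locus definition;
    LD score regression for SNP heritability and cross-trait genetic
    correlation with observed/liability scale conversion; Wakefield
    approximate-Bayes-factor finemapping with credible sets, single-causal
    colocalisation, and configuration-enumeration TWAS gene finemapping;
    LD-aware gene and competitive gene-set association with Cauchy (ACAT)
    combination; a two-sample Mendelian-randomisation estimator suite with
    mixture-model instrument clustering; and pathway-partitioned
    (pharmagenic enrichment) polygenic scoring with genome-wide-PRS-adjusted
    association testing. A liability-threshold synthetic-data generator with
    block-wise LD produces every input with known ground truth, so the whole
    pipeline is exercisable and testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
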