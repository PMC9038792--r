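Package: lohscape
Title: Genomic Loss-of-Heterozygosity Scoring and Cohort Association
    Analysis for Leiomyosarcoma
Version: 0.1.0
Authors@R:
    person("lohscape", "maintainers", email = "lohscape@example.org",
           role = c("aut", "cre"))
Description: Computes percent genomic loss of heterozygosity (gLOH), a
    homologous-recombination-deficiency scar, from SNP allele observations
    and copy-number segments: log-ratio profiling against a process-matched
    reference, joint changepoint segmentation of log-ratio and folded
    B-allele frequency, tumor purity/ploidy grid fitting, per-segment
    allele-specific integer copy-number (Ci, Mi) estimation, LOH calling
    with whole-chromosome/arm and ambiguity exclusions, and the percent
    gLOH formula.  Adds cohort-level tools: ranked-distribution
    inflection-point cutoff detection, gLOH-high classification,
    gene-alteration association screens with Bonferroni correction,
    differential prevalence and mutual-exclusivity tests, and Kaplan-Meier
    / Cox survival analysis.  A synthetic-data module generates panel-scale
    tumor genomes and cohorts with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
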