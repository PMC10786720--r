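Package: molqtl
Title: Multi-Tissue Molecular QTL Mapping, Sharing and GWAS Integration
Version: 0.9.0
Authors@R:
    person("molqtl", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested pipeline for molecular quantitative
    trait locus (molQTL) analysis: seeded simulation of multi-breed genotypes
    with LD, count-scale molecular phenotypes and intron-excision clusters
    with planted effects; phenotype preparation (TPM, expression filters,
    TMM, inverse normal transformation, PSI filters, hidden-factor and
    genotype-PC covariates); cis and trans QTL mapping with adaptive
    permutations, beta-approximated empirical p-values and two-layer FDR;
    conditionally independent signals, allelic fold change and single-causal
    ABF fine-mapping; genotype-by-context interaction QTL; multi-tissue
    sharing statistics (fixed-effect meta-analysis, m-values, pairwise effect
    correlations, Storey's pi1, clustering similarity); GWAS integration
    (cohort meta-analysis, locus definition, enrichment, colocalization,
    SMR/HEIDI, TWAS training and summary association, annotation and TAD
    enrichment); and cross-species comparison at the orthologous-gene level
    including meta-TWAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
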