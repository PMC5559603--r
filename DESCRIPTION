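Package: reqtlkit
Title: Response eQTL Mapping and Characterization in Stimulated Immune Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping and characterizing response expression
    quantitative trait loci (reQTLs) in immune cells stimulated with
    microbial ligands.  Provides per-condition cis-eQTL scans with
    adaptive permutations and beta-approximated empirical p-values,
    slope-comparison (z-test) reQTL calling with treatment and time-point
    specificity, constant-eQTL definition, temporal-dynamics
    classification with differential-expression congruence tests,
    MAF/LD-matched resampling nulls for positive-selection statistics
    (iHS, SDS), derived-allele direction analysis, Storey pi1 replication
    estimates, GWAS-catalog LD overlap, and stratified Q-Q enrichment
    curves.  A fully synthetic cohort generator with planted eQTL/reQTL
    architectures and known ground truth makes every stage testable
    without access to cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    limma,
    stats,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
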