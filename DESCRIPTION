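Package: herdimpute
Title: Genotyping-Array Tagging and Imputation Accuracy in Diverged and
    Admixed Cattle Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess how well SNP genotyping arrays capture and
    impute the genetic variation of diverged and admixed cattle
    populations. Provides a Balding-Nichols / haplotype-copying cohort
    simulator with array ascertainment and functional-impact annotation,
    VCF and manifest input/output, allele harmonization (strand flips,
    ref/alt swaps, ambiguous-site discards) and coordinate remapping,
    site/sample/relatedness quality control with a KING-robust kinship
    estimator, windowed linkage-disequilibrium tagging statistics and LD
    decay curves, a Li-Stephens hidden Markov model imputation engine
    with leave-one-out dosages (empirical R2) and masked-site dosage R2,
    and an experiment driver for panel-composition and two-step
    (low-density to high-density to sequence) imputation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
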