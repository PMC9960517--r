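Package: iterprs
Title: Iterative Aggregation Pipeline for Polygenic Risk Score Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs stabilized polygenic risk scores (PRS) for quantitative
    traits by repeated train/test resampling of a genotyped cohort. Each
    iteration derives covariate-adjusted per-SNP summary statistics, builds a
    clumping + p-value-thresholding score on the held-out samples, and records
    its incremental R-squared; SNPs recurring across iterations are aggregated
    with averaged effects, candidate scores are ranked by a size-penalized
    R-squared, and the final score is assessed against the empirical baseline
    distribution by bootstrap. Includes multi-cohort genotype harmonization
    (strand flips, allele switches), regression and k-nearest-neighbour
    genotype imputation, variant and sample quality control with an exact
    Hardy-Weinberg test, PCA-based stratification correction with Tracy-Widom
    selection of significant components, PLINK 1 BED/BIM/FAM input/output, and
    a synthetic-cohort generator with known causal architecture for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
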