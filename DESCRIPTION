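Package: parallelEDR
Title: Error Discovery Rate via Parallel Negatives for Many-Hypothesis
    Differential Expression Testing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Error Discovery Rate (EDR), a per-gene Type-I
    error estimate for differential-expression testing that counts the
    "parallel negatives" -- genes whose p-values mirror the rejection
    region at the opposite tail of the p-value distribution -- instead of
    the total number of null genes used by family-wise and false-discovery
    corrections. Includes the reality factor adjustment that inflates the
    error of low-expressed or low-fold-change genes, the classical
    multiplicity corrections it is benchmarked against (Bonferroni, Holm,
    Hochberg, step-down Sidak, Benjamini-Hochberg, Benjamini-Yekutieli,
    Storey q-values, PCER, PFER), a two-group simulation generator with a
    known fraction of differentially expressed genes, and power, ROC and
    precision-recall evaluation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, BiocGenerics
Suggests: testthat (>= 3.0.0), optparse, jsonlite, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: MultipleComparison, DifferentialExpression, Microarray,
    StatisticalMethod
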