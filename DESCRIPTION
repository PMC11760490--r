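Package: grlgwas
Title: GRAMMAR-Lambda Genome-Wide Association Analysis for Backcross Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage genome-wide association analysis for quantitative
    traits in structured (backcross family) populations. Fits a polygenic
    null model by restricted maximum likelihood on a genomic relationship
    matrix, scans GBLUP residuals against each SNP by simple regression,
    recalibrates the deflated chi-squared statistics with a genomic-control
    factor (GRAMMAR-Lambda), and refines candidate QTNs with a
    backward-regression joint analysis. Includes SNP quality control,
    within-family covariate adjustment of phenotypes, a backcross-family
    phenotype/genotype simulator, PLINK bed/bim/fam input and output,
    candidate-gene window annotation, and Manhattan/QQ plot data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
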