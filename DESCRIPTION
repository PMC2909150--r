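Package: snpsetassoc
Title: SNP-Set Association Analysis for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and association testing of unweighted additive
    SNP-set (polygenic) scores against quantitative cognitive measures.
    Provides genotype input/output for PLINK text, VCF and a simple TSV
    dialect; genotype quality control (per-plex individual call rates,
    SNP call rates, Hardy-Weinberg exact testing); direction-coded
    additive scoring with a mean-substitution policy for missing
    genotypes; phenotype standardization, sex/age residualization and
    composite construction; one-tailed Pearson association tests with
    Bonferroni correction and regress-out specificity analyses; QTL
    association power calculations; and a synthetic-cohort generator
    that embodies a generalist-genes (pleiotropic) covariance structure
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
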