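Package: admixscan
Title: Admixture Mapping of Quantitative Traits in Two-Way Admixed Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for admixture mapping of quantitative traits (modelled on
    coronary artery calcification) in two-way admixed family cohorts such as
    African Americans. Provides a synthetic admixed-cohort simulator
    (ancestry tracks, genotypes, pedigrees, zero-inflated phenotypes), sample
    and marker quality control, rank-based inverse-normal (Blom)
    transformation within sex by age strata, pedigree kinship construction,
    kinship-adjusted mixed-model scans of phenotype on local and global
    ancestry, estimation of the effective number of independent ancestry
    tests from autoregressive spectral density at frequency zero, target
    region delimitation with ancestry-informative-marker filtering and
    region-specific Bonferroni thresholds, and conditional adjustment for
    candidate loci via linkage-disequilibrium proxies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
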