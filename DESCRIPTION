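Package: anaerGS
Title: Genomic Selection of Donors for Anaerobic Germination Tolerance in Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening rice donors for tolerance to anaerobic
    (flooded) conditions during germination. Implements the full analysis
    chain for alpha-lattice screening trials: plot-level phenotype
    preparation with Bonferroni outlier screening, SNP marker quality
    control, the VanRaden genomic relationship matrix, single-experiment
    and multi-environment linear mixed models solved by REML and
    Henderson's mixed-model equations, genomic estimated breeding values
    (GBLUP), broad-sense heritability and reliability, a weighted
    selection index over eight germination and seedling-vigour traits,
    and ranked donor lists under anaerobic, aerobic and across-environment
    selection rules. A synthetic trial generator with known ground truth
    supports validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools
Suggests: testthat (>= 3.0.0), vcfR, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
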