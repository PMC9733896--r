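Package: mixscan
Title: Genome-Wide Diversity and Frequency Association Scans for Varietal Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how within-plot genetic diversity affects the
    performance of multi-way crop varietal mixtures. Builds balanced unique
    k-way mixture designs from a panel of inbred lines, imputes per-mixture
    allele frequencies and Nei expected heterozygosity from line genotypes,
    runs per-SNP genome-wide frequency (GWFA) and diversity (GWDA) association
    scans by sequential type-I ANOVA with treatment-by-genetics interactions,
    corrects for multiplicity with the Galwey effective number of tests,
    delimits QTL intervals by average-linkage clustering of Hill-Robertson
    linkage disequilibrium, and censuses genome-wide diversity-slope signs
    across watering regimes, including a paired Wilcoxon test of the
    stress-gradient hypothesis. A synthetic-data module simulates line
    genotypes with LD-block structure and plot-level phenotypes so the whole
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
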