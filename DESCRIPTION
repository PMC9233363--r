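Package: mitomethyl
Title: Mitochondrial DNA Methylation Indices, Epigenetic Clock, and
    Drug-Use Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cytosine-level bisulfite-sequencing calls
    from the circular mitochondrial genome: coverage and presence filtering,
    CpG/CHG/CHH context annotation on both strands, per-site statistics
    (paired Wilcoxon, covariate-adjusted logistic and linear models),
    construction of weighted methylation indices contrasting brain areas,
    tracking chronological age, and detecting illicit drug use, an
    ordinary-least-squares epigenetic clock with age-acceleration estimates,
    and threshold/ROC evaluation of the drug-use classifier. Includes a
    synthetic-data generator with planted effect sites so the full pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
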