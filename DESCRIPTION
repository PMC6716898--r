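Package: stoichioprot
Title: Stoichioproteomic Analysis of Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stoichioproteomics: computing amino-acid side-chain
    elemental composition (oxygen and carbon frequencies, C:O ratios) of
    protein sequences, converting ordinal immunohistochemistry staining
    annotations to expression scores, selecting highly and lowly expressed
    protein sets, classifying differentially expressed proteins by log2
    expression ratio with exact rank-sum significance and false discovery
    rate gates, comparing element-content distributions between protein
    sets with Kolmogorov-Smirnov and Tukey statistics, counting
    differentially expressed genes per chromosome, and generating synthetic
    proteomes and expression matrices with planted oxygen-usage effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
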