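Package: ideoselect
Title: Multi-Trait Drought-Selection Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for screening crop genotypes for drought tolerance in
    multi-environment trials run under contrasting water regimes. Provides an
    alpha-lattice trial simulator with known ground truth, REML variance
    components with broad-sense heritability and genotype BLUEs, the eight
    classical drought-tolerance indices (STI, GMP, MP, HM, TOL, SSI, YSI, YI)
    with rank-sum screening, the multi-trait genotype-ideotype distance index
    (MGIDI) with factor analysis, predicted selection gains and per-factor
    strengths and weaknesses, plus genotype-by-index biplot decomposition,
    correlation analyses and selection-set comparison. All user-facing
    functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
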