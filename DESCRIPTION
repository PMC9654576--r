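Package: behavdiv
Title: Behavioral Diversity Indices for Ethogram Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the standard alpha-diversity indices used to quantify
    the richness and evenness of animal behavior from ethogram-coded
    observation records: behavioral richness, the Shannon-Wiener index, the
    three Simpson indices (D, index of diversity, reciprocal), Menhinick's
    and Margalef's richness indices, the Chao1 estimator of unobserved
    behavior categories, and the Behavioral Variety Index against an
    expected wild-type repertoire. Includes tidy aggregation of raw scan
    records into count tables, deterministic scenario sweeps that
    characterize each index's sensitivity to richness, evenness and
    sampling effort, ggplot2 visualisation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
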