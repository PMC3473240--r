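Package: gozipf
Title: Zipf's-Law Analysis of Gene Ontology Annotation Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats Gene Ontology (GO) annotation sets as a text corpus and
    analyses their term-usage statistics with the tools of quantitative
    linguistics. Reads GAF 2.x annotation files and OBO 1.2 ontologies,
    stratifies corpora by sub-ontology and evidence-code class, fits discrete
    power laws to term-frequency distributions by maximum likelihood with
    Kolmogorov-Smirnov lower-cutoff selection and a semi-parametric bootstrap
    goodness-of-fit test, converts between the Zipf, frequency power-law and
    Pareto exponents, relates term usage frequency to ontology depth, and
    compares fitted exponents across corpora. Includes a synthetic-corpus
    generator with known exponent, evidence-code profile and depth-frequency
    coupling so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
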