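Package: targetodds
Title: Probabilistic Models of Drug Target Identification and Development Success
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Closed-form probability models of drug development viewed as a
    discovery problem over the sample space of gene-disease pairings: Bayes-rule
    false/true discovery rates for preclinical experiments, a linked
    preclinical-clinical two-stage success model with forward prediction and
    back-calculation from observed success rates, parallel-programme and
    hypergeometric target-portfolio arithmetic, repurposing probabilities from
    shared causal genes, and binomial rediscovery/yield calculations for
    genome-wide association studies. Every closed form is paired with a seeded
    Monte-Carlo simulator of the underlying gene-by-disease causal world.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
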