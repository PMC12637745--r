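Package: llmrr
Title: Repeatability and Reproducibility Metrics for Large Language Model Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the run-to-run variability of large language model
    generations with four scores on [0, 1]: semantic repeatability and
    reproducibility, computed from pairwise cosine similarity of sequence
    embeddings, and internal repeatability and reproducibility, computed from
    the Shannon entropy of per-position top-k token distributions under
    temperature-scaled sampling. Reads run logs in a JSON Lines dialect close
    to commercial completion-API responses, compares groups of score pairs
    with a permutation-based multivariate Kruskal-Wallis test, and ships a
    seeded simulator of synthetic run logs with known ground-truth dispersion
    so every metric is testable by parameter recovery without any model
    access.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
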