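Package: retlang
Title: Cross-Lingual Retweet Influence and Diffusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how (mis)information spreads between two
    language communities on a retweet network. Builds monthly retweet
    networks and ranks users by unique-retweeter degree, measures
    month-over-month churn of the influencer set with Rank Biased Overlap,
    propagates pro/anti stance labels from seed users through the retweet
    graph by a majority-retweet rule, and analyses cross-lingual URL
    diffusion: per-community popularity, non-native URL sharing, first-post
    and peak-diffusion day differences, and maximum-likelihood fitting of an
    asymmetric Laplace distribution to the timing data. Includes a synthetic
    bilingual corpus generator with known ground truth so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
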