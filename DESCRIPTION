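Package: sniffr
Title: Optimal Olfactory Search with Alternation Between Ground and Air Sniffing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the emergence of 'alternation' -- a searcher pausing to
    sniff in the air while otherwise moving and sniffing the ground -- as a
    consequence of optimal olfactory search in turbulent odor plumes. Provides
    synthetic per-sniff detection-probability maps for two sensing heights, a
    grid POMDP with dual-modality observation likelihoods and Bayesian belief
    filtering, a Perseus-style point-based value-iteration solver with
    alpha-vector value representation, episode simulation and behavioural
    analyses (cast/surge segmentation, air-sniff rates, excess path length,
    belief entropy traces), and the analytic marginal-value-theory model of
    cast-sniff-surge search including the depth-limited cast-and-sniff
    planner and episode value recursions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
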