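Package: contestevo
Title: Runaway Evolution of Signals, Body Size and Aggression via
    Male-Male Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative-genetic model of sexual selection driven by
    male-male contests. A male signal mediates aggression in pairwise
    duels through socially contingent trait expression (an indirect
    genetic effect), and game-theoretic costs and benefits generate
    nonsocial and social selection gradients. The package provides the
    deterministic response-to-selection recursion for the population
    means of signal, body size and aggression, closed-form equilibria
    with a line-of-equilibria stability analysis and runaway
    classification, an individual-based contest simulator that generates
    dyadic fitness data, regression estimators that recover selection
    gradients and the behavioural responsiveness coefficient from such
    data, and static comparators for the female-choice (Fisher-Lande)
    runaway parallel.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
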