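Package: nanopbpk
Title: Physiologically Based Pharmacokinetic and Biopharmaceutics Modelling of Nanocrystal Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Whole-body physiologically based pharmacokinetic (PBPK) simulation in rat and
    human coupled to a compartmental absorption and transit model of the gastrointestinal
    tract, in which oral input is driven by particle dissolution (Wang-Flanagan rate law)
    from a binned product particle size distribution (P-PSD). Includes an in vitro USP II
    dissolution simulator with inverse P-PSD fitting, dissolution metrics (dissolution
    efficiency, f2 similarity, crystallinity degree), noncompartmental analysis and
    fold-error validation statistics, Monte Carlo virtual-population simulation, and
    one-at-a-time parameter sensitivity analysis. Ships a fully parameterised efavirenz
    nanocrystal case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
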