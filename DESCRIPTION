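Package: brandevo
Title: Generative Inference and Averaging Analysis for Combinatorial
    Ownership Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the cultural evolution of registered
    ownership marks (cattle brands) built from a finite alphabet of
    graphic components. Provides an agent-based model of yearly brand
    creation under frequency-dependent component copying and complexity
    pressure, a nine-statistic diversity summary suite (Hill numbers,
    Jaccard and Morisita-Horn beta diversity, edit distance), random-
    forest approximate Bayesian computation for inferring copying
    strength and complexity, a shuffling-model predictor of component
    combination prevalence, and mixed-model comparisons of structured
    versus time- and space-averaged registries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ranger,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
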