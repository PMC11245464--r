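Package: cfn3
Title: Closed-Form Maximum Likelihood Estimation for Three-Leaf Trees
    under the CFN Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic maximum likelihood estimation of branch lengths for
    unrooted three-leaf phylogenetic trees under the two-state symmetric
    Cavender-Farris-Neyman (CFN) substitution model.  Implements the CFN
    forward model (site-pattern probabilities, Hadamard conjugation, Fourier
    coordinates and the model's semi-algebraic constraints), sufficient
    statistics and genericity diagnostics for observed data, the closed-form
    global maximizer of the likelihood over the closed parameter cube
    including the complete taxonomy of boundary solutions (branches estimated
    at length zero or infinity), a seeded sequence simulator, and an
    independent numerical likelihood-maximization oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
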