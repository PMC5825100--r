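Package: sempic
Title: Phylogenetic Path Analysis of Extra-Pair Paternity by Structural
    Equation Modeling on Independent Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood path analysis (structural equation
    modeling over observed variables) for comparative data, with and
    without transformation to Felsenstein's phylogenetically independent
    contrasts.  Ships the six a-priori path models relating eight
    life-history, morphological and bioacoustic traits to rates of
    extra-pair paternity in passerines, fit-index machinery (chi-square,
    AIC, CFI, RMSEA), standardized direct and indirect (mediated)
    effects with delta-method inference, a composite song-complexity
    score, and a seeded generator of Yule trees and Brownian-motion
    trait data obeying arbitrary linear structural equations, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
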