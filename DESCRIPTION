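Package: fitscape
Title: Forward-in-Time Substitution Simulation Under Fluctuating Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gillespie simulation of the substitution process along a rooted
    phylogeny in which the single-position fitness landscape itself changes
    over time. Scaled fitness vectors and a mutation-rate matrix are converted
    into instantaneous substitution rate matrices and stationary distributions
    under a mutation-selection model; landscapes may change stochastically as
    a Poisson process, deterministically at evenly spaced epochs (shared or
    independent across parallel lineages), or at user-specified branch
    coordinates, with new landscapes obtained by resampling, permutation,
    explicit specification, or shifting the fitness of the resident allele.
    Sequences are reported at every node of the tree together with an optional
    log of landscape-change events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
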