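Package: redqueen
Title: Multiallelic Viability Selection in a Deteriorating Environment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructionist Monte Carlo simulations of single-locus,
    multiallelic viability selection with recurrent mutation, in constant or
    gradually deteriorating (Red Queen) environments, with or without
    Wright-Fisher genetic drift.  Provides the one-generation dynamics
    (selection, mutant introduction, multinomial drift, extinction pruning),
    two mutant-fitness generators (independent uniform viabilities and
    generalized dominance), deterministic and stochastic fitness decay, census
    statistics (common-allele counts, the evenness statistic I with its
    broken-stick null distribution, fitness-structure summaries), and the
    classical random-fitness-set equilibrium scan (feasibility and spectral
    stability of interior equilibria) used as a parameter-space baseline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
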