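Package: islandassembly
Title: Likelihood Inference and Simulation of Island Community Assembly
Version: 0.1.0
Authors@R:
    person("Island", "Assembly Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the macroevolutionary assembly of insular
    communities from dated phylogenies. Fits a stochastic model in which each
    mainland species independently colonises an island (immigration), and its
    island descendants speciate anagenetically or cladogenetically, go extinct,
    or are replaced by re-immigrants; cladogenesis and immigration rates may
    decline linearly with clade diversity towards a carrying capacity. Provides
    the hidden-state master-equation likelihood for colonisation and branching
    times, maximum-likelihood fitting with multi-start optimisation and
    AIC/BIC model comparison, an exact continuous-time (Gillespie) simulator
    of community assembly, parametric-bootstrap precision estimates, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
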