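Package: phygen
Title: Generalized Bayesian Phylogenetics with Shared and Multifurcating Divergences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Bayesian inference of rooted phylogenies in a
    generalized tree space that allows two or more lineages to diverge at
    the same time (shared divergences) and single lineages to diverge into
    more than two descendants (multifurcations). Couples the generalized
    tree model with a multispecies coalescent likelihood for biallelic
    characters that analytically integrates over gene trees and mutational
    histories, reversible-jump Markov chain Monte Carlo samplers over tree
    models of varying dimension, a coalescent simulator of gene trees and
    characters, and posterior summaries including split, node and
    shared-divergence frequencies, branch-score tree distances, and the
    ASDSF, PSRF and ESS convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
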