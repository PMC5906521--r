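Package: branchca
Title: Lattice Simulation and Approximate Bayesian Inference of Kidney
    Explant Branching Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A cellular-automaton model of ureteric bud branching in
    cultured kidney explants. Epithelial cells on a square lattice move and
    divide under the control of a quasi-steady diffusible growth-factor
    (GDNF) field with Dirichlet far-field boundary conditions; cell
    division is gated by a probit switch on the local dimensionless GDNF
    concentration and both chemotaxis and anisotropic cell division are
    modelled as softmax-biased site selection. The package also provides
    the matching morphometrics (medial-axis skeleton branch-point counts
    and normalised explant area) and an Approximate Approximate Bayesian
    Computation (AABC) scheme that infers the division-switch and motility
    parameters from summary-statistic trajectories using a pilot library
    of true simulations, Epanechnikov-kernel weights and Dirichlet
    resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
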