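Package: crnreduce
Title: Multiscale Model Reduction of Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing deterministic mass-action reaction networks with
    separated rate constants. Implements graph-rewriting reduction of
    monomolecular networks (pruning of dominated reactions, cutting of cycles at
    the limiting step, gluing of cycles with quasi-stationary renormalization)
    together with the 0-1 spectral approximation of the resulting acyclic
    deterministic digraphs; tropicalization of polynomial vector fields, tropical
    manifolds in two variables, Filippov sliding-mode tests and hybrid
    (piecewise-smooth) simulation; detection of slaved species by comparing
    trajectories with imposed trajectories and their classification into
    quasi-equilibrium (QE) and quasi-steady-state (QSS) species by monomial
    pruning; and QSS/QE network rewriting based on exact integer kernels of the
    fast stoichiometric matrix (species pools, elementary flux modes), with
    symbolic rate recalculation and tracking of effective parameters as monomials
    of the original rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
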