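Package: netreduce
Title: Combined Model Reduction for Controlled Biochemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated model-order reduction of controlled (input-output)
    biochemical reaction network models described by stiff, nonlinear ordinary
    differential equations. Ingests SBML Level 2/3 models into a control-affine
    state-space form, locates conserved moieties by Householder-QR analysis of
    the stoichiometry matrix and eliminates the slowest conserved species,
    reduces stiffness by forward-selection proper lumping under a Galerkin
    projection (with steady-state, time-averaged and Moore-Penrose lumping
    inverses), and finishes with empirical balanced truncation built from
    perturbed simulations. Also provides nondimensionalisation scoring,
    per-state empirical controllability/observability importance indices, and
    seed-deterministic synthetic fixtures (linear time-invariant systems with
    analytic Gramians, conserved mass-action networks, and a stiff
    ligand-controlled phosphorelay) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
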