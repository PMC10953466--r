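Package: crnosc
Title: Oscillation Analysis of Small Mass-Action Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether small chemical reaction networks with
    mass-action kinetics can oscillate. Provides exact structural predicates
    (rank, molecularity, trivial species, dynamical nontriviality via positive
    kernel vectors with Stiemke witnesses), reduced-Jacobian stability formulas
    for three-reaction rank-two systems (including a Cauchy-Binet expansion of
    the reduced Jacobian determinant), the complete Andronov-Hopf / center
    classification of planar quadratic three-reaction systems, a general
    decision procedure for quadratic trimolecular three-reaction systems with
    any number of species, numerical first focal values, ODE simulation with
    periodicity detection, and an exhaustive enumeration engine that produces
    censuses of oscillatory networks up to species relabelling.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
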