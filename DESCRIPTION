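Package: crnbif
Title: Exact Bifurcation Census of Planar Quadratic Mass-Action Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates planar (two-species) mass-action reaction networks with
    up to four reactions, bimolecular reactant complexes and trimolecular
    product complexes, reduces them modulo dynamical equivalence, and decides
    by exact symbolic computation which networks admit fold, Andronov-Hopf,
    Bautin and Bogdanov-Takens bifurcations of positive equilibria.  All
    feasibility decisions (determinant sign analysis on the positive kernel
    cone of the stoichiometric matrix, focal values L1-L3, Bogdanov-Takens
    normal-form coefficients) are made in exact rational arithmetic with
    Sturm-sequence real-root isolation, so the reported census counts are
    certified rather than numerical.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Rcpp, jsonlite
LinkingTo: Rcpp, BH
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
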