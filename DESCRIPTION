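Package: mpolyindex
Title: M-Polynomials, Degree-Based Topological Indices, and QSPR Models for
    Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes M-polynomials of hydrogen-suppressed molecular graphs
    and derives nine degree-based topological indices (first and second
    Zagreb, modified second Zagreb, general and inverse Randic, symmetric
    division degree, harmonic, inverse-sum-indeg, augmented Zagreb) via an
    exact-rational bivariate operator calculus as well as by direct edge
    sums.  Ships parametric edge partitions for the guar gum polysaccharide
    family and its hydroxypropyl, carboxymethyl and carboxymethyl-
    hydroxypropyl derivatives with linear-in-n closed forms, packaged edge
    partitions and physicochemical properties for eight carbohydrates, and
    linear, quadratic and logarithmic QSPR regression with r, r-squared,
    F and p reporting.  Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
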