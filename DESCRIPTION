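Package: ecguq
Title: Shape Uncertainty Quantification for the Forward and Inverse
    Problems of Electrocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Boundary-integral tools for the potential-based forward and
    inverse problems of electrocardiography on two-dimensional torso
    cross-sections, with quantification of space-time shape uncertainty of
    the pericardial boundary.  Closed boundary curves are represented by
    trigonometric polynomials and the torso Laplace problem is discretised
    by a spectrally accurate Nystrom collocation method with a
    desingularised logarithmic-kernel quadrature.  The ill-posed inverse
    problem (pericardial potential from chest recordings) is solved with
    zero- and first-order Tikhonov, H1/2 and linearised total-variation
    regularisation with L-curve parameter selection.  Shape uncertainty is
    modelled as a periodic-in-time random deformation field with a
    Matern-by-sine-power covariance, compressed by a pivoted Cholesky
    Karhunen-Loeve expansion, and moments of chest and pericardial
    potentials are estimated by anisotropic sparse Gauss-Legendre
    quadrature validated against Halton quasi-Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
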