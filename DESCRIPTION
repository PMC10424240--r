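Package: gstrain
Title: Multi-Frequency EPR Line-Width and g-Strain Analysis of Nitroxide
    Spin Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuous-wave EPR powder spectrum simulation for S = 1/2
    nitroxide radicals coupled to a single 14N nucleus (I = 1), ensemble
    spectrum synthesis from per-snapshot g- and hyperfine tensors,
    geometric hydrogen-bond classification of solvation trajectories,
    multicomponent multi-frequency global spectral fitting, and
    quantification of g-strain from the frequency dependence of apparent
    Gaussian line widths via quadrature decomposition and through-origin
    regression (ppm slope).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
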