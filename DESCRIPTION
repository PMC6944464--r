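Package: lvreduce
Title: Low-Order Models of Left-Ventricular Mechanics by Congruency Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates left-ventricular contraction with a low-order model that
    couples a single biophysical myofilament unit to organ-level pressure and
    volume through trained linear transformations, embedded in lumped atrial
    and 3-element Windkessel hemodynamics. Provides multi-element (parallel and
    series) generalizations used as a pseudo-high-fidelity reference, the
    two-stage congruency-training procedure (passive coefficient fit and
    derivative-free active fit of the congruency error), Latin-hypercube
    sampling of idealized ventricular anatomies with Gaussian-process
    regression from geometry to trained coefficients, and inverse estimation
    of cell and hemodynamic parameters from clinical contraction indices
    (ejection fraction, ejection time, isovolumic relaxation time, aortic
    pulse pressure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    lhs,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
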