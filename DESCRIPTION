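Package: fgsopt
Title: Mechanobiology-Driven Porosity Optimization of Functionally Graded Bone Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs the porosity gradient of open-porous functionally graded
    scaffolds for bone tissue engineering by coupling a parametric two-phase
    (scaffold + granulation tissue) finite element model, a quasi-static Biot
    poroelastic solver, the Prendergast mechano-regulation model of tissue
    differentiation, and a bound-constrained sequential quadratic programming
    optimizer. Piecewise-linear pore-radius laws (constant, linear, bi-linear,
    tri-linear) are tuned to maximize the scaffold volume predicted to be
    occupied by mature bone under compression, shear or mixed loading.
    Includes analytical validation fixtures (Terzaghi consolidation column,
    drained patch test), a full-factorial study driver, and tidy accessors and
    plots for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
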