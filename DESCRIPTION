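Package: nsetr
Title: Nanometal Surface Energy Transfer Modelling for Metal
    Nanoparticle-Dye Quenching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models fluorescence quenching of a dye donor by a metal
    nanosphere acceptor under the nanometal surface energy transfer (NSET)
    mechanism and its Forster resonance energy transfer (FRET) counterpart.
    Provides size-corrected Drude dielectric functions with interband
    corrections, Mie-theory extinction cross-sections and molar extinction
    coefficients, the NSET 50%-quenching distance d0 and the Forster radius
    R0, rigid-rod DNA-ruler geometry for donor-acceptor separations, an
    exhaustive grid-search fitter for the scattering constant C and the
    orientation prefactor alpha with MRE/RMSE error surfaces, a synthetic
    case-table generator emulating the DNA-ruler study design, and a
    Lasso/multilayer-perceptron regression harness with split, k-fold and
    blind-holdout validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    nnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
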