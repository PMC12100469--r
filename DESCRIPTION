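Package: pbmcdose
Title: Deep-Learning Conversion of Proton Pencil-Beam Dose to Monte-Carlo-Quality Dose
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts analytical pencil-beam (PB) proton dose distributions for
    single fields into Monte-Carlo-quality (MC) dose using a hierarchically
    dense 3D U-Net, with beam-frame canonicalization (rotation of CT and dose
    about the isocenter to a fixed gantry/couch angle), zooming augmentation,
    and fold-ensemble inference.  Includes a synthetic heterogeneous phantom
    and paired PB-like/MC-like spread-out-Bragg-peak dose simulator for
    end-to-end experiments, and a dosimetric evaluation suite: global 3D
    gamma analysis, beam's-eye-view range maps with average range difference
    (R90/R50), mean absolute error, isodose-band Dice coefficients, and
    DVH metrics with relative dose errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
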