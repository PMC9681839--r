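Package: picswbc
Title: White Blood Cell Detection, Classification and Segmentation from
    Quantitative Phase Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing white blood cells (WBCs)
    in label-free quantitative phase images of blood smears. Reconstructs
    the quantitative phase map from four pi/2-shifted interferograms
    (spatial light interference microscopy), translates phase images into
    Wright-stain brightfield renderings with a conditional GAN, localises
    and classifies neutrophils, eosinophils, lymphocytes and monocytes
    with a compact anchor-based detector, produces binary WBC masks with a
    U-Net, fuses boxes and masks into per-pixel semantic maps, combines an
    ensemble of five model pairs by pixel-wise majority voting, and
    evaluates everything with mean average precision and pixel-wise
    precision/recall/F1. A seeded synthetic blood-smear simulator provides
    phase maps, interferograms, brightfield renderings and full ground
    truth, so the whole pipeline runs without clinical data. All networks
    are trained with a small built-in convolutional engine (Rcpp
    backpropagation), sized for CPU use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
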