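Package: melrad
Title: FDG-PET Radiomic Modelling of One-Year Progression-Free Status in
    Metastatic Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to build and evaluate a pre-treatment FDG-PET radiomic
    classifier of one-year progression-free status in metastatic melanoma
    treated with immune checkpoint inhibitors. Provides PERCIST-style
    liver-referenced tumour segmentation of SUV volumes, extraction of an
    856-feature radiomic vector (first-order, shape, GLCM, GLRLM, GLSZM,
    GLDM and NGTDM classes on the original image and eight undecimated
    coif1 wavelet sub-bands), reference-batch empirical-Bayes (ComBat)
    harmonization of multi-centre feature tables, a two-step Mann-Whitney /
    Spearman feature screen, a cross-validated multilayer-perceptron
    classifier with importance-ranked backward elimination and an
    efficiency-maximizing probability threshold, Kaplan-Meier / log-rank /
    Cox survival stratification, and a synthetic-data module emulating the
    two-centre study design so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    survival,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
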