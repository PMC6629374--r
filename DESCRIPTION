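Package: viphys
Title: Biophysical Modelling and Patch-Clamp Analysis of VIP Interneuron
    Firing Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley simulation of vasoactive
    intestinal peptide expressing cortical interneurons (VIP-INs) with an
    added slow, M-like potassium conductance; current-clamp and
    voltage-clamp feature extraction (spike detection, rheobase, firing
    frequencies, passive properties, spike rundown); unsupervised
    classification of irregular-spiking (IS) versus continuous-adapting
    (CA) firing phenotypes by k-means on burst length and interspike
    interval variability; synthetic cohort generation emulating wild-type
    and Scn1a haploinsufficient (Dravet syndrome model) recordings,
    including KCNQ-channel pharmacology; and the accompanying group
    statistics (2x2 chi-square, Mann-Whitney U, dendritic vertical bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
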