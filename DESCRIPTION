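Package: kmdclass
Title: Biogenicity Classification of Complex Organic Mixtures from
    Kendrick Mass Defect Histogram Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts ultrahigh-resolution mass-spectrometry peak lists of
    complex organic mixtures into mass x log-abundance x Kendrick-mass-defect
    histogram "images", and classifies sample origin (Biological, Meteorite,
    Petroleum, Synthetic) by principal component analysis followed by
    multinomial logistic regression under stratified k-fold cross-validation.
    Also enumerates diketopiperazine and saturated-fatty-acid target masses
    and matches them against measured peak lists at ppm tolerance, renders
    KMD-slice RGB views and van Krevelen diagrams, and generates labelled
    synthetic spectra with class-typical homologous-series structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
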