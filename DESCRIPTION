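Package: CaOxQuant
Title: Quantitative Phase Analysis of Calcium Oxalate Kidney Stones from
    FTIR, Micro-CT and Powder XRD Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the calcium oxalate monohydrate (COM) and dihydrate
    (COD) content of kidney stones from three complementary measurements.
    The core method decomposes the shared 780 cm-1 infrared absorption peak
    geometrically into COM and COD contributions and inverts a two-branch
    linear calibration to weight fractions. Supporting tools cover
    Kramers-Kronig conversion of specular reflectance spectra, atmospheric
    H2O/CO2 subtraction, two comparison FTIR analyses (910/780 band ratio
    and 1324 cm-1 peak shift), attenuation-based COM/COD mapping of
    micro-CT slices, and characteristic-peak phase identification in powder
    diffraction patterns. A synthetic-data module generates mixture
    spectra, reflectance spectra, calibration standards, CT phantoms and
    diffraction patterns with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    S4Vectors,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Spectroscopy, Preprocessing, Classification
RoxygenNote: 7.3.3
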