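Package: metsir
Title: Dual Classification of Metabolic Syndrome from FTIR Plasma Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for discriminating metabolic syndrome (MetS)
    from mid-infrared plasma spectra. Provides spectral preprocessing
    (replicate averaging, Savitzky-Golay smoothing and derivatives, standard
    normal variate, extended multiplicative scatter correction, region
    restriction, mean centering), an NCEP-ATP-III rule engine for MetS
    labelling, NIPALS principal component analysis, stepwise orthogonalization
    variable selection (SELECT) with a Fisher class-separation weight,
    two-class linear discriminant analysis with leave-one-out cross-validation,
    and SIMCA class modelling with F-test class spaces, modelling and
    discriminant power, interclass distance and Cooman coordinates. A synthetic
    generator produces paired clinical tables and FTIR-like spectra with
    band-metabolite links so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
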