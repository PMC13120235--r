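Package: blendspec
Title: Infrared Fingerprinting of Plant-Product Blends with Binary PLS-DA
    and PLS Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for identifying targeted plant varieties
    in blended products from NIR or MID-IR spectra and estimating their
    proportions. Implements NIPALS PLS1 regression and binary PLS-DA,
    six spectral pre-treatments (autoscaling, standard normal variate,
    Savitzky-Golay first and second derivatives, and SNV-derivative
    combinations), duplex sample-set partitioning, 10-fold cross-validation
    with latent-variable selection, RPD/RER model evaluation, trituration-based
    limit-of-detection estimation, and screening of unknown commercial-like
    samples. Includes a synthetic spectra generator emulating highly similar
    endmembers, equal-proportion mixture designs, trituration series and
    instrumental artefacts (multiplicative scatter, affine baseline, noise).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
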