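Package: nirclass
Title: Robust Chemometric Classification of Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A chemometric workflow for discriminating sample classes
    (e.g. plant genotypes) from near-infrared diffuse-reflectance
    spectra. Provides spectral preprocessing (Savitzky-Golay smoothing
    and second derivative, standard normal variate), robust principal
    component analysis with score/orthogonal-distance outlier diagnosis
    applied per class, Kennard-Stone representative train/test
    splitting, multiclass partial least squares discriminant analysis
    with Monte-Carlo cross-validation and an F-test rule for selecting
    the number of latent variables, per-class sensitivity/specificity
    evaluation, and a synthetic three-class NIR spectrum generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
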