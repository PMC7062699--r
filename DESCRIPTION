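Package: nutrispec
Title: Leaf Nutrient Estimation from Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates leaf nitrogen, phosphorus and potassium content
    (mg per g dry matter) from 350-1000 nm leaf reflectance spectra.
    Builds exhaustive two-band spectral indices (ten formula families over
    reflectance and first-derivative spectra), maps their Pearson
    correlation with leaf nutrients over all band pairs, ranks sensitive
    wavelengths by significance counts, fits stepwise linear models on the
    selected bands, and benchmarks against a registry of 43 published
    empirical vegetation indices including red-edge parameters. Ships a
    synthetic spectra generator emulating a 6-species x 3-degradation x
    8-replicate field design so the whole pipeline is testable without
    field data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
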