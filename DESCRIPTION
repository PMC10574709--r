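Package: nmrpattern
Title: Chemometric Pattern Recognition for 1H-NMR Herbal Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for authenticating herbal material from
    1D 1H-NMR fingerprints, built around the classification of Lonicerae
    japonicae flos (honeysuckle, cultivated and wild) against its common
    adulterant Lonicerae flos.  Provides spectral bucketing with TMS
    normalization, NIPALS principal component analysis with Wold
    cross-validated Q2, PLS-DA and OPLS-DA latent-variable classifiers with
    VIP scores, S-line marker diagnostics and permutation-test validation,
    a two-stage VIP-intersection variable-selection cascade, and stepwise
    Fisher linear discriminant analysis with leave-one-out cross-validation.
    A Lorentzian line-shape cohort simulator generates labelled synthetic
    spectra with the marker structure of the saponin and secoiridoid regions,
    so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
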