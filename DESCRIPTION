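Package: riverpa
Title: Upstream Protected-Area Cover and Temporal Change in River Invertebrate Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to relate temporal change in river invertebrate communities
    (abundance, taxon richness, and Ecological Quality Ratio) to protected-area
    cover across multiple upstream spatial scales. Provides planar river-network
    delineation of buffered upstream corridors (1-, 10-, 100-km) and full
    upstream catchments, time-lagged protected-area cover and gain-rate
    computation, AR(1) generalized least squares trend estimation with
    percent-per-year conversion, linear mixed model group comparisons with
    likelihood-ratio tests and Benjamini-Hochberg correction, penalized
    additive models with tensor-product interactions between protection and
    initial ecological quality, and a synthetic-study generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    mgcv,
    rlang,
    stats,
    utils
Suggests:
    nlme,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
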