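Package: ateem
Title: Absorbance and Excitation-Emission Matrix Chemometrics for Beverage Authenticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for combined absorbance and fluorescence excitation-emission
    matrix (A-TEEM) analysis of beverages: inner-filter-effect correction,
    Rayleigh scatter excision, non-negative PARAFAC decomposition with core
    consistency and split-half diagnostics, principal component exploration,
    and two-class partial least squares discriminant analysis with variable
    importance in projection maps. Includes a synthetic A-TEEM data generator
    emulating direct versus thermally processed strawberry beverages, and an
    end-to-end pipeline that reproduces the full classification study on
    simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
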