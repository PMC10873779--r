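Package: fedmed
Title: Federated Analytics and Learning for Multi-Site Clinical Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator of a hospital federated research
    network: site nodes holding de-identified FHIR/DICOM data, an
    orchestration hub restricted to whitelisted, schema-validated,
    audited aggregate exchanges, disclosure-controlled federated
    summary statistics with random-effects meta-analysis
    (DerSimonian-Laird), cryptographic pseudonymization (PBKDF2) and
    DICOM whitelist scrubbing, and federated training (FedSGD/FedAVG)
    of a multi-input tabular + image mortality model, exercised
    end-to-end on synthetic multi-site cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr
Config/testthat/edition: 3
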