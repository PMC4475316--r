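Package: ecgsqc
Title: ECG Signal Quality Classification from Lead-Covariance Eigenvalues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the clinical quality of short multi-lead ECG records
    from the eigenvalue spectrum of the 8x8 cross-covariance matrix of the
    independent leads (I, II, V1-V6). Clean records concentrate their energy
    in a low-rank cardiac signal subspace, while disconnected leads collapse
    the spectrum and high-power artifacts inflate it; three published
    threshold-rule classifiers (CART, C4.5 and RIPPER rule lists over the
    log10 eigenvalues) map the spectrum to an Acceptable/Unacceptable label.
    Includes a WFDB format-16 and CSV reader for digitized records, a
    synthetic 8-lead ECG generator with labeled noise and artifact
    contamination, a CART-style threshold-tree inducer with a stratified
    k-fold cross-validation harness, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
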