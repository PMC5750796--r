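Package: ewhk
Title: Entropy-Weighted Local-Hyperplane k-Nearest-Neighbour Classification of FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for diagnostic classification of Fourier transform infrared
    (FTIR) absorbance spectra of tissue biopsies. Implements the entropy-weight
    local-hyperplane k-nearest-neighbour classifier (EWHK) and its unweighted
    HKNN special case: per-feature weights are derived from the Shannon entropy
    of each wavenumber channel across the training set, and a query is assigned
    to the class whose local affine hull of weighted nearest neighbours it lies
    closest to, under a ridge-regularised weighted metric. Includes
    Savitzky-Golay smoothing and region-wise standard normal variate (SNV)
    preprocessing, a reader and writer for a flat CSV spectra format, a
    synthetic two-class FTIR spectra generator with realistic band structure,
    and a repeated stratified-split evaluation harness reporting sensitivity,
    specificity, predictive values and accuracy.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
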