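Package: midcorrect
Title: Natural Isotope Abundance and Tracer Impurity Correction for
    Stable Isotope Labeling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects mass spectrometric measurements from stable isotope
    labeling experiments for naturally occurring stable isotopes and for
    isotopic impurity of the tracer substrate. Supports nominal-resolution
    MS1 data, MS/MS transition data where label can reside in both the
    product ion and the neutral loss, and high-resolution multiple-tracer
    data (e.g. simultaneous 13C/15N). For each molecule a probability
    matrix is assembled from binomial/multinomial isotope distributions
    and the measured vector is deconvolved by non-negative least squares.
    Includes a reverse-mode simulator that generates uncorrected data from
    known corrected values, for validation and for planning experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
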