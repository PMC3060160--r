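Package: itdcode
Title: Frequency-Invariant Coding of Interaural Time Differences in Brainstem Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical modelling of frequency-dependent interaural time
    difference (ITD) tuning in auditory brainstem neurons and of its readout
    by neural populations. Fits cyclic-Gaussian tone delay functions,
    estimates characteristic phase and characteristic delay by
    circular-linear regression, computes single-cell mutual information
    between ITD and firing rate marginalised over stimulus frequency under a
    head-geometry ITD prior and a logarithmic variance-mean noise model, and
    compares two population readouts: a labelled-line code built from
    one-vs-one linear maximum-margin classifiers and a bilateral
    (two-channel) rate-difference code with a linear ITD estimator.
    Includes a synthetic-population generator emulating the statistical
    structure of gerbil dorsal nucleus of the lateral lemniscus recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
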