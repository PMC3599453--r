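Package: gammabg
Title: Normal-Gamma Background Correction for Single-Channel Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based background correction for single-channel microarray
    intensities using a normal-gamma convolution model: the observed intensity
    of each probe is the sum of a gamma-distributed hybridization signal and
    normally distributed background noise, with negative control probes
    providing a pure-noise sample. Provides the FFT-based convolution density,
    joint maximum-likelihood estimation over regular and negative probes,
    conditional-expectation signal recovery, the normal-exponential (normexp)
    baselines (MLE, RMA, NP) and background subtraction, detection-p-value
    utilities including negative-probe inference, quantile normalization, a
    synthetic-array simulator, and an evaluation toolkit (penalized irregular
    histograms, L1 fit distance, mean-absolute-deviation excess-risk ratios,
    absolute-deviation profiles, operating characteristics, and rank-based AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
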