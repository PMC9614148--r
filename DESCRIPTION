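Package: prvdetect
Title: Life-Threatening Arrhythmia Detection from Pulse Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects the four life-threatening arrhythmias (extreme
    bradycardia, extreme tachycardia, ventricular tachycardia, ventricular
    flutter) from continuous arterial blood pressure waveforms. Provides
    integer-coefficient notch and low-pass filters for powerline, baseline
    drift and EMG noise removal, pulse-peak detection and pulse-rate
    variability extraction, a 19-statistic feature battery (time-domain,
    autoregressive LF/HF ratio, Poincare plot, sample/permutation/Shannon
    entropy), random-forest feature selection, decision-tree, extreme
    learning machine and back-propagation neural-network classifiers, and
    Cohen's kappa based evaluation under a repeated 80/20 hold-out
    protocol. A synthetic blood-pressure generator with ground-truth beat
    annotations supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    signal,
    randomForest,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
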