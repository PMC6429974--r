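Package: pulsestage
Title: Staging Progressive Central Hypovolemia from the Arterial Pressure Waveform
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tracks progressive central hypovolemia toward presyncope from the
    noninvasive arterial blood-pressure waveform. Segments continuous finger
    pressure tracings into beats, resamples each beat to a fixed-length
    33-sample shape vector by monotone cubic Hermite interpolation,
    parametrizes beat morphology by principal component analysis, and stages
    beats into four ordinal hypovolemia classes with a soft-margin linear
    support vector machine (one-vs-one). Ships the leave-one-subject-out
    bootstrap evaluation protocol (10 random 10% subsamples per fold, 20-beat
    moving-average smoothing, model averaging, per-class accuracy and mean
    squared error, Cohen's kappa, median [IQR] cohort tables) and a synthetic
    hemodynamic cohort generator emulating lower-body negative pressure
    protocols ending in presyncope or tolerance, so the full pipeline is
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    yaml,
    jsonlite,
    data.table,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
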