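Package: mrcpdetect
Title: Simulation and Single-Trial Detection of Movement-Related Cortical
    Potentials in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing self-paced movement-imagination EEG
    experiments in which the imagination onset is recovered from a
    Libet-style scroller report.  Provides a synthetic-session generator
    (trial/event schedules, condition-dependent ERP templates, a
    Bereitschaftspotential-like MRCP template, 1/f background noise, blink
    artifacts), offline cleaning (zero-phase notch and Butterworth
    band-pass filters, trial-based artifact rejection, PCA plus extended
    Infomax ICA with EOG-guided component removal and back-projection),
    cue-locked ERP statistics (t-percentile bootstrap confidence intervals
    and family-wise-error-controlling tmax permutation tests), IO-locked
    MRCP averaging with peak-negativity detection, time-locked MI-vs-REST
    classification with shrinkage-regularised linear discriminant analysis
    under repeated stratified cross-validation with adjusted-Wald chance
    bounds, and a simulated-online asynchronous detector evaluated
    trial-wise against a structured-permutation chance level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
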