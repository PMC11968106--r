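Package: infraslow
Title: Infraslow Oscillation Analysis for Sleep Photometry and Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing infraslow oscillations (ISO, ~1-2 cycles/min)
    in population calcium and neuromodulator signals recorded across sleep/wake
    cycles in rodents. Provides EEG/EMG-based sleep scoring with microarousal
    detection, isosbestic dF/F preprocessing of dual-channel fiber photometry,
    sliding-window infraslow spectral analysis, trough/peak event detection with
    state-transition outcome classification, microarousal-aligned PSTH latency
    and drop estimation, state-resolved dual-site correlation, and two-photon
    single-cell dF/F and NREM up/down classification. A synthetic session
    generator with known ground truth supports end-to-end parameter-recovery
    validation of the full pipeline.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
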