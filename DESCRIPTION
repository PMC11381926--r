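Package: usprf
Title: Pulse-Repetition-Frequency Tuning Analysis for Ultrasound
    Neuromodulation Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium imaging of transcranial
    ultrasound neuromodulation at physiologic pulse repetition frequencies
    (PRFs). Provides ground-truthed synthetic session and movie generators,
    donut-background trace extraction and dF/F preprocessing, multitaper
    spectral calcium-event detection, a shuffled-baseline permutation test for
    stimulus modulation with pre-stimulus exclusion, PRF-specificity
    classification, pairwise asymmetric correlation coefficient (ACC) network
    synchrony (sustained and transient), evoked-response shape metrics with a
    two-factor GLM comparison, nonparametric test wrappers (Fisher, Wilcoxon,
    Kruskal-Wallis with Dunn-Sidak, Friedman with Nemenyi), and single-cell UMI
    expression heterogeneity statistics (CPM-style log normalization and
    Cliff's delta with magnitude thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
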