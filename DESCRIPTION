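Package: qeegtova
Title: Quantitative EEG Biomarkers During the Test of Variables of Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative EEG (qEEG) biomarker analysis
    during the Test of Variables of Attention (TOVA): seeded synthetic cohort
    generation (19-channel EEG with controllable spatial covariance structure,
    blink/drift/line artifacts, TOVA schedules and behavioral responses),
    preprocessing (median-filter baseline removal, FIR band-reject, ICA plus
    recursive-least-squares EOG cancellation), event-related epoching and
    behavioral scoring, band power and cordance, trace-normalized covariance
    matrix images, a two-scale approximate-entropy score of those images, and
    the statistical evaluation layer (Mann-Whitney, two-way ANOVA with
    Bonferroni post hoc, Spearman correlation, ROC analysis with combined
    scores, and bootstrap resampling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
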