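Package: dbmarkers
Title: Remote Digital Markers of Facial and Vocal Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extraction and analysis of smartphone-collected digital
    behavioral markers for psychiatric research. Computes vocal acoustic
    markers (vocal intensity, fundamental frequency mean and standard
    deviation, local jitter, harmonics-to-noise ratio, speech prevalence)
    from mono speech recordings after log-MMSE speech enhancement,
    baseline-normalized facial expressivity from framewise facial action
    unit intensity tables, PANSS subscale totals and the Marder negative
    symptom factor from item-level scores, and marker-versus-severity
    Pearson correlation tables with Benjamini-Hochberg adjustment and
    test-retest intraclass correlation. Includes seeded generators for
    synthetic voice audio, action-unit tables, and whole cohorts with
    known ground truth, plus a manifest-driven end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    pracma,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
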