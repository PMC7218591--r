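Package: ddxbayes
Title: Probabilistic Differential Diagnosis over a Curated Symptom-Disease Knowledge Base
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A naive-Bayes differential-diagnosis engine for a closed set of
    diseases parameterized by a curated symptom-disease association matrix,
    together with the full evaluation battery used to validate such engines
    against gold-standard clinical vignettes: top-3 accuracy, per-disease and
    frequency-weighted precision and recall, Jaccard and cosine similarity of
    ranked differentials, and upper-tailed Welch t tests, all stratified by
    presentation specificity. Includes readers and writers for knowledge bases
    (JSON or CSV) and coded vignette studies (JSON lines), a synthetic study
    generator with planted ground truth and simulated noisy raters, and a
    command-line interface for reproducible diagnose/evaluate/simulate runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
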