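Package: lungnodesim
Title: Microsimulation of Lung Nodule Measurement Error and Surveillance Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Monte-Carlo microsimulation of a CT lung-nodule screening
    population. Generates synthetic cohorts of risk-dominant nodules with
    shifted truncated log-normal diameter distributions, assigns size-band
    malignancy prevalence and benign-feature flags, grows malignant nodules
    (Gompertz for solid, linear for sub-solid), simulates measurement by
    readers with additive bias and Gaussian noise (true size, radiologist
    consensus, AI alone, AI-assisted and unassisted radiologists), and runs
    each nodule through a simplified diameter-based British Thoracic Society
    management pathway driven by volume doubling time.  Produces
    disposition-by-timepoint tables, sensitivity/specificity and surveillance
    time summaries, and includes a calibration routine that fits growth
    hyperparameters to target true-size sensitivities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
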