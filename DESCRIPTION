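Package: bleedrisk
Title: Bleeding Risk Scores, Time in Therapeutic Range and Prediction
    Evaluation for Anticoagulated Atrial Fibrillation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the HAS-BLED, ATRIA, ORBIT, HEMORR2HAGES and
    CHA2DS2-VASc clinical risk scores and their labile-INR (TTR < 65%)
    modified variants for atrial fibrillation patients on vitamin-K
    antagonists; quantifies anticoagulation quality by the Rosendaal
    linear-interpolation time in therapeutic range; and evaluates score
    performance against ISTH major bleeding with odds ratios,
    Kaplan-Meier / log-rank / Cox survival analysis, ROC c-indexes with
    DeLong comparison, Pencina net reclassification and integrated
    discrimination improvement, Hosmer-Lemeshow calibration and decision
    curve analysis. Includes a calibrated synthetic cohort generator so
    the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
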