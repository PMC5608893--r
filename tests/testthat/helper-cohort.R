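# Builders for baseline records and tiny cohorts used across test files.

# one-or-more fully specified baseline rows; every risk flag defaults to
# absent so tests state only what they switch on
make_patients <- function(n = 1, ...) {
  p <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    sex = "male", age = 50L,
    hypertension = FALSE, uncontrolled_hypertension = FALSE,
    diabetes = FALSE, heart_failure = FALSE, prior_stroke_tia = FALSE,
    hepatic_impairment = FALSE, renal_impairment = FALSE,
    severe_renal_disease = FALSE, egfr_lt60 = FALSE,
    hemoglobin = 14.5, anemia = FALSE,
    coronary_artery_disease = FALSE, smoking = FALSE,
    alcohol_excess = FALSE, antiplatelet_or_nsaid = FALSE,
    malignancy = FALSE, prior_major_bleed = FALSE, rebleed_history = FALSE,
    platelet_defect = FALSE, genetic_cyp2c9 = FALSE, fall_risk = FALSE,
    followup_years = 5, bled = FALSE,
    bleed_day = NA_integer_, bleed_site = NA_character_,
    bleed_fatal = NA, hb_drop = NA_real_, units_transfused = NA_integer_,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  # keep hemoglobin consistent with an anemia override unless the test
  # explicitly pinned both
  if (!is.null(over$anemia) && is.null(over$hemoglobin))
    p$hemoglobin <- ifelse(p$anemia, 10.5, p$hemoglobin)
  p
}

make_inr <- function(patient_id, day, inr) {
  data.frame(patient_id = patient_id, day = day, inr = inr,
             stringsAsFactors = FALSE)
}

# small 3-patient cohort with INR series, used by the I/O tests
make_small_cohort <- function() {
  p <- make_patients(3)
  p$hemoglobin[2] <- NA  # exercise the empty-cell convention
  p$anemia[2] <- TRUE
  p$bled[3] <- TRUE
  p$bleed_day[3] <- 400L
  p$bleed_site[3] <- "gastrointestinal"
  p$bleed_fatal[3] <- FALSE
  p$hb_drop[3] <- 2.5
  p$units_transfused[3] <- 1L
  inr <- make_inr(rep(c("T001", "T002", "T003"), times = c(2, 2, 2)),
                  day = c(0, 30, 0, 40, 0, 25),
                  inr = c(2.5, 2.6, 1.8, 3.2, 2.2, 2.9))
  new_cohort(p, inr)
}
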