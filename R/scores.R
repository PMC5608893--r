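# Clinical bleeding-risk scores for anticoagulated AF patients, with the
# labile-INR (TTR < 65%) modified variants. Per-criterion definitions follow
# the scores' original publications; every awarded point is auditable
# through the component breakdown.

.score_thresholds <- c(
  HASBLED = 3L, ATRIA = 4L, ORBIT = 3L, HEMORR2HAGES = 2L,
  ATRIA_TTR = 4L, ORBIT_TTR = 3L, HEMORR2HAGES_TTR = 2L,
  CHA2DS2VASC = NA_integer_
)

.score_max_points <- c(
  HASBLED = 9L, ATRIA = 10L, ORBIT = 7L, HEMORR2HAGES = 12L,
  ATRIA_TTR = 11L, ORBIT_TTR = 8L, HEMORR2HAGES_TTR = 13L,
  CHA2DS2VASC = 9L
)

.require_flags <- function(patients, cols, score) {
  for (col in cols) {
    if (any(is.na(patients[[col]])))
      stop(sprintf("%s: criterion '%s' missing for patient(s) %s",
                   score, col,
                   paste(utils::head(
                     patients$patient_id[is.na(patients[[col]])], 3),
                     collapse = ", ")),
           call. = FALSE)
  }
}

# Component matrices: one row per patient, one integer column per criterion.
# points = rowSums; category = step function of points at the score's
# published action threshold.

.hasbled_components <- function(patients, labile_inr) {
  .require_flags(patients, c("uncontrolled_hypertension", "renal_impairment",
                             "hepatic_impairment", "prior_stroke_tia",
                             "prior_major_bleed", "antiplatelet_or_nsaid",
                             "alcohol_excess"), "HASBLED")
  if (any(is.na(labile_inr)))
    stop("HASBLED: criterion 'labile_inr' missing (undefined TTR)", call. = FALSE)
  cbind(
    uncontrolled_hypertension = as.integer(patients$uncontrolled_hypertension),
    abnormal_renal            = as.integer(patients$renal_impairment),
    abnormal_liver            = as.integer(patients$hepatic_impairment),
    stroke                    = as.integer(patients$prior_stroke_tia),
    bleeding_history          = as.integer(patients$prior_major_bleed),
    labile_inr                = as.integer(labile_inr),
    elderly_gt65              = as.integer(patients$age > 65),
    antiplatelet_or_nsaid     = as.integer(patients$antiplatelet_or_nsaid),
    alcohol_excess            = as.integer(patients$alcohol_excess)
  )
}

.atria_components <- function(patients) {
  .require_flags(patients, c("severe_renal_disease", "prior_major_bleed",
                             "hypertension"), "ATRIA")
  anemia <- resolve_anemia(patients)
  if (any(is.na(anemia)))
    stop("ATRIA: anemia unresolvable (no flag, no hemoglobin) for patient(s) ",
         paste(utils::head(patients$patient_id[is.na(anemia)], 3), collapse = ", "),
         call. = FALSE)
  cbind(
    anemia               = 3L * as.integer(anemia),
    severe_renal_disease = 3L * as.integer(patients$severe_renal_disease),
    age_ge75             = 2L * as.integer(patients$age >= 75),
    prior_bleeding       = as.integer(patients$prior_major_bleed),
    hypertension         = as.integer(patients$hypertension)
  )
}

.orbit_components <- function(patients) {
  .require_flags(patients, c("prior_major_bleed", "egfr_lt60",
                             "antiplatelet_or_nsaid"), "ORBIT")
  anemia <- resolve_anemia(patients)
  if (any(is.na(anemia)))
    stop("ORBIT: anemia unresolvable for patient(s) ",
         paste(utils::head(patients$patient_id[is.na(anemia)], 3), collapse = ", "),
         call. = FALSE)
  cbind(
    age_ge75         = as.integer(patients$age >= 75),
    anemia           = 2L * as.integer(anemia),
    bleeding_history = 2L * as.integer(patients$prior_major_bleed),
    egfr_lt60        = as.integer(patients$egfr_lt60),
    antiplatelet     = as.integer(patients$antiplatelet_or_nsaid)
  )
}

.hemorr2hages_components <- function(patients) {
  .require_flags(patients, c("hepatic_impairment", "renal_impairment",
                             "alcohol_excess", "malignancy", "platelet_defect",
                             "rebleed_history", "uncontrolled_hypertension",
                             "genetic_cyp2c9", "fall_risk",
                             "prior_stroke_tia"), "HEMORR2HAGES")
  anemia <- resolve_anemia(patients)
  if (any(is.na(anemia)))
    stop("HEMORR2HAGES: anemia unresolvable for patient(s) ",
         paste(utils::head(patients$patient_id[is.na(anemia)], 3), collapse = ", "),
         call. = FALSE)
  cbind(
    hepatic_or_renal   = as.integer(patients$hepatic_impairment |
                                      patients$renal_impairment),
    ethanol_abuse      = as.integer(patients$alcohol_excess),
    malignancy         = as.integer(patients$malignancy),
    age_gt75           = as.integer(patients$age > 75),
    platelet_defect    = as.integer(patients$platelet_defect),
    rebleeding         = 2L * as.integer(patients$rebleed_history),
    uncontrolled_htn   = as.integer(patients$uncontrolled_hypertension),
    anemia             = as.integer(anemia),
    genetic_cyp2c9     = as.integer(patients$genetic_cyp2c9),
    fall_risk          = as.integer(patients$fall_risk),
    stroke             = as.integer(patients$prior_stroke_tia)
  )
}

.cha2ds2vasc_components <- function(patients) {
  .require_flags(patients, c("heart_failure", "hypertension", "diabetes",
                             "prior_stroke_tia", "coronary_artery_disease"),
                 "CHA2DS2VASC")
  cbind(
    heart_failure    = as.integer(patients$heart_failure),
    hypertension     = as.integer(patients$hypertension),
    age_ge75         = 2L * as.integer(patients$age >= 75),
    diabetes         = as.integer(patients$diabetes),
    stroke_tia       = 2L * as.integer(patients$prior_stroke_tia),
    vascular_disease = as.integer(patients$coronary_artery_disease),
    age_65_74        = as.integer(patients$age >= 65 & patients$age <= 74),
    female           = as.integer(patients$sex == "female")
  )
}

.component_matrix <- function(score_name, patients, labile_inr = NULL) {
  switch(score_name,
    HASBLED          = .hasbled_components(patients, labile_inr),
    ATRIA            = .atria_components(patients),
    ORBIT            = .orbit_components(patients),
    HEMORR2HAGES     = .hemorr2hages_components(patients),
    CHA2DS2VASC      = .cha2ds2vasc_components(patients),
    ATRIA_TTR        = ,
    ORBIT_TTR        = ,
    HEMORR2HAGES_TTR = {
      base <- sub("_TTR$", "", score_name)
      if (is.null(labile_inr) || any(is.na(labile_inr)))
        stop(score_name, ": labile_inr flag required", call. = FALSE)
      cbind(.component_matrix(base, patients),
            labile_inr = as.integer(labile_inr))
    },
    stop("unknown score: ", score_name, call. = FALSE)
  )
}

.category_from_points <- function(score_name, points) {
  thr <- .score_thresholds[[score_name]]
  if (is.na(thr)) return(rep(NA_character_, length(points)))
  ifelse(points >= thr, "high_or_medium_high", "low")
}

.score_result <- function(score_name, comp_row) {
  points <- sum(comp_row)
  stopifnot(points <= .score_max_points[[score_name]])
  structure(list(
    score_name = score_name,
    points = as.integer(points),
    category = .category_from_points(score_name, points),
    component_breakdown = comp_row
  ), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<%s> %d point(s)%s\n", x$score_name, x$points,
              if (is.na(x$category)) "" else paste0(" [", x$category, "]")))
  nz <- x$component_breakdown[x$component_breakdown > 0]
  if (length(nz) > 0)
    cat("  ", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

.one_patient <- function(patient) {
  if (inherits(patient, "bleed_cohort")) patient <- patient$patients
  stopifnot(is.data.frame(patient), nrow(patient) == 1)
  patient
}

#' HAS-BLED score
#'
#' One point each for: uncontrolled hypertension (SBP > 160 mmHg), abnormal
#' renal function, abnormal liver function, prior stroke/TIA, bleeding
#' history, labile INR (TTR below the control threshold, default 65%),
#' age > 65, concomitant antiplatelet/NSAID, alcohol excess. Maximum 9.
#' Action category: points >= 3 is high risk.
#'
#' @param patient One-row baseline data.frame (or a one-patient cohort).
#' @param labile_inr Logical: TTR < 65% (computed upstream, see
#'   [rosendaal_ttr()] and [labile_flag()]).
#' @return A `score_result`: points, category and per-criterion breakdown.
#' @export
compute_hasbled <- function(patient, labile_inr) {
  p <- .one_patient(patient)
  .score_result("HASBLED", .hasbled_components(p, labile_inr)[1, ])
}

#' ATRIA bleeding score
#'
#' Anemia 3, severe renal disease (dialysis or eGFR < 30) 3, age >= 75 2,
#' prior bleeding 1, hypertension 1; maximum 10. Medium/high category at
#' points >= 4. Anemia is taken from the explicit flag or derived from
#' hemoglobin ([derive_anemia()]); unresolvable anemia is an error.
#'
#' @inheritParams compute_hasbled
#' @return A `score_result`.
#' @export
compute_atria <- function(patient) {
  p <- .one_patient(patient)
  .score_result("ATRIA", .atria_components(p)[1, ])
}

#' ORBIT bleeding score
#'
#' Age >= 75 1, anemia/abnormal hemoglobin 2, bleeding history 2,
#' eGFR < 60 mL/min 1, antiplatelet treatment 1; maximum 7. Medium/high
#' category at points >= 3.
#'
#' @inheritParams compute_hasbled
#' @return A `score_result`.
#' @export
compute_orbit <- function(patient) {
  p <- .one_patient(patient)
  .score_result("ORBIT", .orbit_components(p)[1, ])
}

#' HEMORR2HAGES bleeding score
#'
#' One point each for hepatic or renal disease, ethanol abuse, malignancy,
#' age > 75, reduced platelet count/function, uncontrolled hypertension,
#' anemia, genetic factors (CYP2C9), excessive fall risk and stroke, plus
#' two points for rebleeding history; maximum 12. Medium/high category at
#' points >= 2.
#'
#' @inheritParams compute_hasbled
#' @return A `score_result`.
#' @export
compute_hemorr2hages <- function(patient) {
  p <- .one_patient(patient)
  .score_result("HEMORR2HAGES", .hemorr2hages_components(p)[1, ])
}

#' CHA2DS2-VASc stroke score (descriptive)
#'
#' Cardiac failure 1, hypertension 1, age >= 75 doubled, diabetes 1,
#' stroke/TIA doubled, vascular disease 1, age 65-74 1, female sex 1.
#' Vascular disease maps to coronary artery disease, the only vascular
#' field carried in the baseline table. No bleeding-risk category.
#'
#' @inheritParams compute_hasbled
#' @return A `score_result` (category `NA`).
#' @export
compute_cha2ds2vasc <- function(patient) {
  p <- .one_patient(patient)
  .score_result("CHA2DS2VASC", .cha2ds2vasc_components(p)[1, ])
}

#' TTR-modified variant of a bleeding score
#'
#' Adds one point for labile INR (TTR < 65%) to the ATRIA, ORBIT or
#' HEMORR2HAGES score, leaving the category threshold unchanged -- so the
#' extra point can flip a borderline patient from low to medium/high risk.
#'
#' @param base One of "ATRIA", "ORBIT", "HEMORR2HAGES".
#' @inheritParams compute_hasbled
#' @return A `score_result` named `<base>_TTR`.
#' @export
compute_modified_score <- function(base, patient, labile_inr) {
  base <- match.arg(base, c("ATRIA", "ORBIT", "HEMORR2HAGES"))
  p <- .one_patient(patient)
  .score_result(paste0(base, "_TTR"),
                .component_matrix(paste0(base, "_TTR"), p, labile_inr)[1, ])
}

#' Score a whole cohort
#'
#' Vectorised scoring of every requested score over the baseline table.
#'
#' @param cohort A `bleed_cohort` (or its baseline data.frame).
#' @param labile_inr Logical vector, one per patient (required for HASBLED
#'   and the `_TTR` variants).
#' @param scores Character vector of score names.
#' @return Tidy data.frame: `patient_id`, `score_name`, `points`,
#'   `category`, `breakdown` (pipe-delimited `criterion=points` pairs for
#'   awarded criteria).
#' @export
score_cohort <- function(cohort, labile_inr = NULL,
                         scores = c("HASBLED", "ATRIA", "ORBIT",
                                    "HEMORR2HAGES", "ATRIA_TTR", "ORBIT_TTR",
                                    "HEMORR2HAGES_TTR", "CHA2DS2VASC")) {
  patients <- if (inherits(cohort, "bleed_cohort")) cohort$patients else cohort
  out <- lapply(scores, function(s) {
    comp <- .component_matrix(s, patients, labile_inr)
    points <- as.integer(rowSums(comp))
    breakdown <- apply(comp, 1, function(r) {
      nz <- r[r > 0]
      if (length(nz) == 0) "" else
        paste(sprintf("%s=%d", names(nz), nz), collapse = "|")
    })
    data.frame(patient_id = patients$patient_id, score_name = s,
               points = points,
               category = .category_from_points(s, points),
               breakdown = breakdown, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify a bleed against the ISTH major-bleeding criteria
#'
#' Major iff fatal, or in a critical site (intracranial or other critical
#' area/organ), or causing a hemoglobin fall of >= 2 g/dL, or leading to
#' transfusion of >= 2 units. A pure disjunction; missing fields default to
#' non-qualifying.
#'
#' @param event List or one-row data.frame with fields `site`, `fatal`,
#'   `hb_drop`, `units_transfused` (any may be `NULL`/`NA`).
#' @return Logical flag.
#' @export
classify_isth_major <- function(event) {
  g <- function(field, default) {
    v <- event[[field]]
    if (is.null(v) || length(v) == 0 || is.na(v)) default else v
  }
  isTRUE(g("fatal", FALSE)) ||
    g("site", "other") %in% c("intracranial", "other_critical") ||
    g("hb_drop", 0) >= 2.0 ||
    g("units_transfused", 0L) >= 2L
}
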