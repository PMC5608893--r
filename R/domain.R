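# Data model for anticoagulated AF cohorts: one baseline table (one row per
# patient) and one long INR table (patient_id, day, inr). Dates are integer
# day offsets from each patient's entry; 1 year = 365.25 days everywhere.

DAYS_PER_YEAR <- 365.25

#' Baseline table column dictionary
#'
#' Fixed column order of the baseline CSV written and read by
#' [write_cohort()] / [read_cohort()]. Risk-factor flags are stored 0/1;
#' `hemoglobin` and the bleed-event columns may be empty (missing).
#'
#' @format Character vector of column names.
#' @export
baseline_columns <- c(
  "patient_id", "sex", "age",
  "hypertension", "uncontrolled_hypertension", "diabetes", "heart_failure",
  "prior_stroke_tia", "hepatic_impairment", "renal_impairment",
  "severe_renal_disease", "egfr_lt60", "hemoglobin", "anemia",
  "coronary_artery_disease", "smoking", "alcohol_excess",
  "antiplatelet_or_nsaid", "malignancy", "prior_major_bleed",
  "rebleed_history", "platelet_defect", "genetic_cyp2c9", "fall_risk",
  "followup_years", "bled",
  "bleed_day", "bleed_site", "bleed_fatal", "hb_drop", "units_transfused"
)

# required 0/1 flags (anemia is optional: may be derived from hemoglobin)
.flag_columns <- c(
  "hypertension", "uncontrolled_hypertension", "diabetes", "heart_failure",
  "prior_stroke_tia", "hepatic_impairment", "renal_impairment",
  "severe_renal_disease", "egfr_lt60",
  "coronary_artery_disease", "smoking", "alcohol_excess",
  "antiplatelet_or_nsaid", "malignancy", "prior_major_bleed",
  "rebleed_history", "platelet_defect", "genetic_cyp2c9", "fall_risk",
  "bled"
)

.bleed_sites <- c("intracranial", "gastrointestinal", "other_critical", "other")

#' Construct and validate a cohort
#'
#' Bundles a baseline patient table and a long-format INR table into a
#' validated `bleed_cohort` object, the container consumed by every other
#' module.
#'
#' @param patients data.frame with the columns of [baseline_columns]
#'   (logical or 0/1 flags accepted).
#' @param inr data.frame with columns `patient_id`, `day` (integer day
#'   offset from entry, >= 0) and `inr` (positive real in (0.5, 20)).
#' @return An object of class `bleed_cohort`: a list with elements
#'   `patients` and `inr`, both canonicalised data.frames.
#' @export
new_cohort <- function(patients, inr) {
  patients <- .canonical_patients(patients)
  inr <- .canonical_inr(inr)
  cohort <- structure(list(patients = patients, inr = inr),
                      class = "bleed_cohort")
  validate_cohort(cohort)
  cohort
}

#' @export
print.bleed_cohort <- function(x, ...) {
  cat(sprintf("<bleed_cohort> %d patients, %d INR observations, %d major bleeds\n",
              nrow(x$patients), nrow(x$inr), sum(x$patients$bled)))
  invisible(x)
}

.canonical_patients <- function(patients) {
  stopifnot(is.data.frame(patients))
  missing <- setdiff(baseline_columns, names(patients))
  if (length(missing) > 0)
    stop("baseline table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  patients <- as.data.frame(patients)[baseline_columns]
  patients$patient_id <- as.character(patients$patient_id)
  patients$sex <- as.character(patients$sex)
  patients$age <- as.integer(patients$age)
  for (col in c(.flag_columns, "anemia", "bleed_fatal"))
    patients[[col]] <- .as_flag(patients[[col]], col)
  for (col in c("hemoglobin", "followup_years", "hb_drop"))
    patients[[col]] <- as.numeric(patients[[col]])
  patients$bleed_day <- as.integer(patients$bleed_day)
  patients$units_transfused <- as.integer(patients$units_transfused)
  patients$bleed_site <- as.character(patients$bleed_site)
  patients$bleed_site[!is.na(patients$bleed_site) &
                        patients$bleed_site == ""] <- NA_character_
  rownames(patients) <- NULL
  patients
}

.as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & !(x %in% c(0, 1))
  if (any(bad))
    stop(sprintf("column '%s': values must be 0/1 (rows %s)", col,
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  x == 1
}

.canonical_inr <- function(inr) {
  stopifnot(is.data.frame(inr))
  missing <- setdiff(c("patient_id", "day", "inr"), names(inr))
  if (length(missing) > 0)
    stop("INR table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  inr <- as.data.frame(inr)[c("patient_id", "day", "inr")]
  inr$patient_id <- as.character(inr$patient_id)
  inr$day <- as.integer(inr$day)
  inr$inr <- as.numeric(inr$inr)
  inr <- inr[order(inr$patient_id, inr$day), , drop = FALSE]
  rownames(inr) <- NULL
  inr
}

#' Validate a cohort against the data-model invariants
#'
#' Checks every structural invariant (unique ids, referential integrity of
#' the INR table, age and follow-up ranges, flag implications, bleed-event
#' consistency). All violations are reported together with row numbers;
#' nothing is silently dropped.
#'
#' @param cohort A `bleed_cohort`.
#' @return `cohort`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "bleed_cohort"))
  p <- cohort$patients
  i <- cohort$inr
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0)
      problems <<- c(problems, sprintf("%s (rows %s)", msg,
                                       paste(utils::head(rows, 5), collapse = ", ")))
  }

  dup <- which(duplicated(p$patient_id))
  if (length(dup) > 0)
    problems <- c(problems, sprintf(
      "duplicate patient_id: %s",
      paste(unique(p$patient_id[dup]), collapse = ", ")))
  note(which(is.na(p$sex) | !(p$sex %in% c("male", "female"))),
       "sex must be 'male' or 'female'")
  note(which(is.na(p$age) | p$age < 18), "age must be an integer >= 18")
  note(which(is.na(p$followup_years) | p$followup_years <= 0),
       "followup_years must be > 0")
  for (col in .flag_columns)
    note(which(is.na(p[[col]])), sprintf("flag '%s' must be 0/1", col))
  note(which(!is.na(p$hemoglobin) & p$hemoglobin <= 0),
       "hemoglobin must be positive when present")
  note(which(p$severe_renal_disease & !p$renal_impairment),
       "severe_renal_disease implies renal_impairment")
  note(which(p$rebleed_history & !p$prior_major_bleed),
       "rebleed_history implies prior_major_bleed")
  note(which(p$bled & is.na(p$bleed_day)),
       "bled patients must carry a bleed_day")
  note(which(!p$bled & !is.na(p$bleed_day)),
       "bleed_day present for a patient with bled = 0")
  note(which(p$bled & (is.na(p$bleed_site) | !(p$bleed_site %in% .bleed_sites))),
       sprintf("bleed_site must be one of %s", paste(.bleed_sites, collapse = "/")))
  note(which(p$bled & !is.na(p$bleed_day) &
               p$bleed_day > p$followup_years * DAYS_PER_YEAR + 1e-9),
       "bleed_day exceeds followup_years * 365.25")
  note(which(p$bled & !is.na(p$hb_drop) & p$hb_drop < 0),
       "hb_drop must be >= 0")
  note(which(p$bled & !is.na(p$units_transfused) & p$units_transfused < 0),
       "units_transfused must be >= 0")

  orphan <- which(!(i$patient_id %in% p$patient_id))
  if (length(orphan) > 0)
    problems <- c(problems, sprintf(
      "referential error: INR rows for unknown patient_id %s (rows %s)",
      paste(unique(i$patient_id[orphan]), collapse = ", "),
      paste(utils::head(orphan, 5), collapse = ", ")))
  note(which(is.na(i$day) | i$day < 0), "INR day must be an integer >= 0")
  note(which(is.na(i$inr) | i$inr <= 0.5 | i$inr >= 20),
       "inr must lie in (0.5, 20)")
  if (nrow(i) > 1) {
    same <- i$patient_id[-1] == i$patient_id[-nrow(i)]
    dupday <- which(same & i$day[-1] == i$day[-nrow(i)]) + 1L
    note(dupday, "duplicate INR day within a patient")
  }

  if (length(problems) > 0)
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cohort)
}

#' Read a cohort from its two CSV files
#'
#' @param baseline_path CSV, one row per patient, header exactly
#'   [baseline_columns].
#' @param inr_path CSV long format with header `patient_id,day,inr`.
#' @return A validated `bleed_cohort`.
#' @seealso [write_cohort()] for the inverse; the pair round-trips exactly.
#' @export
read_cohort <- function(baseline_path, inr_path) {
  for (path in c(baseline_path, inr_path))
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  patients <- utils::read.csv(baseline_path, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  inr <- utils::read.csv(inr_path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  new_cohort(patients, inr)
}

#' Write a cohort to its two CSV files
#'
#' Missing optional values (hemoglobin, bleed-event fields of non-bleeders)
#' are written as empty cells; flags as 0/1. Column order is fixed
#' ([baseline_columns]) so files are diff-stable.
#'
#' @param cohort A valid `bleed_cohort`.
#' @param baseline_path,inr_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, baseline_path, inr_path) {
  validate_cohort(cohort)
  p <- cohort$patients
  for (col in c(.flag_columns, "anemia", "bleed_fatal"))
    p[[col]] <- as.integer(p[[col]])
  utils::write.csv(p, baseline_path, row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(cohort$inr, inr_path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(c(baseline_path, inr_path))
}

#' Anemia from hemoglobin, by sex
#'
#' Anemia is hemoglobin < 13 g/dL in men and < 12 g/dL in women (strict
#' inequalities; WHO convention). The clinical literature occasionally
#' prints these cut-offs in "g/L" by typo; they are only physiological in
#' g/dL, the unit used throughout this package.
#'
#' @param sex "male"/"female" (vectorised).
#' @param hemoglobin g/dL, positive; `NA` yields `NA` (unknown anemia
#'   status, which downstream scorers refuse).
#' @return Logical vector.
#' @export
derive_anemia <- function(sex, hemoglobin) {
  stopifnot(all(sex %in% c("male", "female")))
  if (any(!is.na(hemoglobin) & hemoglobin <= 0))
    stop("hemoglobin must be positive", call. = FALSE)
  cut <- ifelse(sex == "male", 13.0, 12.0)
  hemoglobin < cut
}

# Resolve per-patient anemia: an explicit adjudicated flag wins over the
# hemoglobin-derived one (registry data often carries adjudicated flags);
# inconsistencies are warned about, both-missing stays NA.
resolve_anemia <- function(patients) {
  derived <- rep(NA, nrow(patients))
  has_hb <- !is.na(patients$hemoglobin)
  derived[has_hb] <- derive_anemia(patients$sex[has_hb],
                                   patients$hemoglobin[has_hb])
  explicit <- patients$anemia
  clash <- !is.na(explicit) & !is.na(derived) & explicit != derived
  if (any(clash))
    warning(sprintf(
      "anemia flag inconsistent with hemoglobin for %d patient(s) (e.g. %s); explicit flag wins",
      sum(clash), paste(utils::head(patients$patient_id[clash], 3), collapse = ", ")),
      call. = FALSE)
  ifelse(is.na(explicit), derived, explicit)
}

# Extract the bleed-event columns of bleeders as a data.frame (one row per
# event), used by the event classifier and rate summaries.
bleed_events <- function(cohort) {
  p <- cohort$patients[cohort$patients$bled, , drop = FALSE]
  data.frame(patient_id = p$patient_id, day = p$bleed_day,
             site = p$bleed_site, fatal = p$bleed_fatal,
             hb_drop = p$hb_drop, units_transfused = p$units_transfused,
             stringsAsFactors = FALSE)
}
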