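# Per-score point assignments, categories, the TTR-modified variants and
# the ISTH major-bleed classifier.

test_that("HAS-BLED awards the nine one-point criteria", {
  p0 <- make_patients(1)
  r <- compute_hasbled(p0, labile_inr = FALSE)
  expect_equal(r$points, 0L)
  expect_equal(r$category, "low")

  r <- compute_hasbled(p0, labile_inr = TRUE)
  expect_equal(r$points, 1L)
  expect_equal(r$category, "low")
  expect_equal(unname(r$component_breakdown["labile_inr"]), 1L)

  all9 <- make_patients(1, age = 70L, uncontrolled_hypertension = TRUE,
                        renal_impairment = TRUE, hepatic_impairment = TRUE,
                        prior_stroke_tia = TRUE, prior_major_bleed = TRUE,
                        antiplatelet_or_nsaid = TRUE, alcohol_excess = TRUE)
  r <- compute_hasbled(all9, labile_inr = TRUE)
  expect_equal(r$points, 9L)
  expect_equal(r$category, "high_or_medium_high")

  # elderly criterion is strictly > 65
  expect_equal(compute_hasbled(make_patients(1, age = 65L), FALSE)$points, 0L)
  expect_equal(compute_hasbled(make_patients(1, age = 66L), FALSE)$points, 1L)
  # missing flag errors, naming the criterion
  expect_error(compute_hasbled(make_patients(1, alcohol_excess = NA), FALSE),
               "alcohol_excess")
})

test_that("ATRIA weights and its >= 4 threshold", {
  expect_equal(compute_atria(make_patients(1))$points, 0L)
  r <- compute_atria(make_patients(1, anemia = TRUE, renal_impairment = TRUE,
                                   severe_renal_disease = TRUE, age = 80L))
  expect_equal(r$points, 8L)
  expect_equal(r$category, "high_or_medium_high")
  r <- compute_atria(make_patients(1, hypertension = TRUE))
  expect_equal(r$points, 1L)
  expect_equal(r$category, "low")
  # category boundary: 3 is low, 4 is medium/high
  expect_equal(compute_atria(make_patients(1, anemia = TRUE))$category, "low")
  expect_equal(compute_atria(
    make_patients(1, anemia = TRUE, hypertension = TRUE, age = 76L))$category,
    "high_or_medium_high")
})

test_that("ORBIT weights and its >= 3 threshold", {
  expect_equal(compute_orbit(make_patients(1))$points, 0L)
  r <- compute_orbit(make_patients(1, anemia = TRUE, prior_major_bleed = TRUE))
  expect_equal(r$points, 4L)
  expect_equal(r$category, "high_or_medium_high")
  r <- compute_orbit(make_patients(1, age = 80L))
  expect_equal(r$points, 1L)
  expect_equal(r$category, "low")
  # age cut-off implemented as >= 75
  expect_equal(compute_orbit(make_patients(1, age = 74L))$points, 0L)
  expect_equal(compute_orbit(make_patients(1, age = 75L))$points, 1L)
})

test_that("HEMORR2HAGES weights, doubled rebleed, >= 2 threshold", {
  expect_equal(compute_hemorr2hages(make_patients(1))$points, 0L)
  r <- compute_hemorr2hages(make_patients(1, prior_major_bleed = TRUE,
                                          rebleed_history = TRUE))
  expect_equal(r$points, 2L)
  expect_equal(r$category, "high_or_medium_high")
  r <- compute_hemorr2hages(make_patients(1, anemia = TRUE, age = 80L))
  expect_equal(r$points, 2L)
  expect_equal(r$category, "high_or_medium_high")
  # hepatic OR renal is a single criterion
  r <- compute_hemorr2hages(make_patients(1, hepatic_impairment = TRUE,
                                          renal_impairment = TRUE))
  expect_equal(r$points, 1L)
  # age criterion is strictly > 75
  expect_equal(compute_hemorr2hages(make_patients(1, age = 75L))$points, 0L)
})

test_that("CHA2DS2-VASc doubled criteria and age bands", {
  expect_equal(compute_cha2ds2vasc(make_patients(1, age = 50L))$points, 0L)
  r <- compute_cha2ds2vasc(make_patients(1, sex = "female", age = 76L,
                                         prior_stroke_tia = TRUE))
  expect_equal(r$points, 5L)
  expect_equal(compute_cha2ds2vasc(make_patients(1, age = 70L))$points, 1L)
  # age >= 75 replaces (not adds to) the 65-74 point
  expect_equal(compute_cha2ds2vasc(make_patients(1, age = 75L))$points, 2L)
})

test_that("TTR-modified scores add exactly one point, threshold unchanged", {
  p <- make_patients(1, anemia = TRUE)  # ATRIA 3
  expect_equal(compute_modified_score("ATRIA", p, TRUE)$points, 4L)
  expect_equal(compute_modified_score("ATRIA", p, TRUE)$category,
               "high_or_medium_high")
  expect_equal(compute_modified_score("ORBIT", make_patients(1), FALSE)$points,
               0L)
  # HEMORR2HAGES 1 point flips low -> high with the labile point
  p <- make_patients(1, malignancy = TRUE)
  expect_equal(compute_hemorr2hages(p)$category, "low")
  m <- compute_modified_score("HEMORR2HAGES", p, TRUE)
  expect_equal(m$points, 2L)
  expect_equal(m$category, "high_or_medium_high")
})

test_that("monotonicity: adding any single criterion never lowers points", {
  flags <- c("hypertension", "uncontrolled_hypertension", "diabetes",
             "heart_failure", "prior_stroke_tia", "hepatic_impairment",
             "renal_impairment", "egfr_lt60", "anemia",
             "coronary_artery_disease", "alcohol_excess",
             "antiplatelet_or_nsaid", "malignancy", "prior_major_bleed",
             "platelet_defect", "genetic_cyp2c9", "fall_risk")
  score_all <- function(p) c(
    compute_hasbled(p, FALSE)$points, compute_atria(p)$points,
    compute_orbit(p)$points, compute_hemorr2hages(p)$points,
    compute_cha2ds2vasc(p)$points)
  base <- score_all(make_patients(1))
  for (fl in flags) {
    args <- stats::setNames(list(TRUE), fl)
    p <- do.call(make_patients, c(list(1), args))
    expect_true(all(score_all(p) >= base), info = fl)
  }
  # labile identity: modified = base + labile
  set.seed(11)
  co <- generate_cohort(synthetic_config(n_patients = 60, seed = 11))
  for (s in c("ATRIA", "ORBIT", "HEMORR2HAGES")) {
    long <- score_cohort(co, labile_inr = rep(TRUE, 60),
                         scores = c(s, paste0(s, "_TTR")))
    pts <- split(long$points, long$score_name)
    expect_equal(pts[[paste0(s, "_TTR")]], pts[[s]] + 1L)
  }
})

test_that("categories partition every scored cohort", {
  co <- generate_cohort(synthetic_config(n_patients = 150, seed = 3))
  labile <- ttr_cohort(co)$labile
  long <- score_cohort(co, labile_inr = labile)
  for (s in setdiff(unique(long$score_name), "CHA2DS2VASC")) {
    cat_counts <- table(long$category[long$score_name == s])
    expect_equal(sum(cat_counts), 150)
  }
  # breakdown always sums to points
  nz <- long[long$breakdown != "", ]
  sums <- vapply(strsplit(nz$breakdown, "|", fixed = TRUE), function(parts)
    sum(as.integer(sub(".*=", "", parts))), numeric(1))
  expect_equal(sums, as.numeric(nz$points))
})

test_that("ISTH major-bleed classifier is a pure disjunction", {
  expect_true(classify_isth_major(list(fatal = TRUE)))
  expect_true(classify_isth_major(list(site = "gastrointestinal",
                                       hb_drop = 2.5)))
  expect_true(classify_isth_major(list(site = "intracranial")))
  expect_true(classify_isth_major(list(units_transfused = 2L)))
  expect_false(classify_isth_major(list(site = "other", hb_drop = 1.0,
                                        units_transfused = 1L,
                                        fatal = FALSE)))
  expect_false(classify_isth_major(list()))
  # boundary: hb fall of exactly 2 g/dL qualifies
  expect_true(classify_isth_major(list(hb_drop = 2.0)))
})
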