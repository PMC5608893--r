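# End-to-end orchestration: simulate or ingest a cohort, compute TTR and
# all scores, then every table/figure analogue (event distribution and
# odds ratios, crude/annualized rates, Kaplan-Meier + log-rank per risk
# category, univariate Cox, c-indexes with DeLong comparisons, NRI/IDI,
# Hosmer-Lemeshow calibration of the modified scores, decision curves).
# Every stage is a pure function of (inputs, config, seed).

#' Pipeline run configuration
#'
#' @param baseline_path,inr_path Input CSVs ([read_cohort()]); `NULL` to
#'   simulate instead.
#' @param simulate A [synthetic_config()] used when no input paths are
#'   given (default: `synthetic_config(seed = seed)`).
#' @param ttr_threshold Labile-INR threshold in percent (default 65).
#' @param out_dir Output directory for TSV/JSON artefacts; `NULL` writes
#'   nothing.
#' @param seed Integer run seed; the simulation consumes a derived
#'   substream so adding stages never perturbs it.
#' @return A `run_config` list.
#' @export
run_config <- function(baseline_path = NULL, inr_path = NULL,
                       simulate = NULL, ttr_threshold = 65,
                       out_dir = NULL, seed = 1L) {
  if (is.null(baseline_path) != is.null(inr_path))
    stop("provide both baseline_path and inr_path, or neither", call. = FALSE)
  if (is.null(baseline_path) && is.null(simulate))
    simulate <- synthetic_config(seed = .substream(seed, "simulate"))
  structure(list(baseline_path = baseline_path, inr_path = inr_path,
                 simulate = simulate, ttr_threshold = ttr_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# deterministic per-stage substream seed derived from the run seed
.substream <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

.base_scores <- c("HASBLED", "ATRIA", "ORBIT", "HEMORR2HAGES")
.modified_scores <- c("ATRIA_TTR", "ORBIT_TTR", "HEMORR2HAGES_TTR")

#' Run the full analysis pipeline
#'
#' @param config A [run_config()].
#' @return An `evaluation_report` list with elements `cohort`, `ttr`,
#'   `scores` (wide points matrix), `rates`, `or_table`,
#'   `distribution_table`, `km` + `log_rank` per score category, `cox`
#'   (continuous and categorical per score), `c_indexes`, `delong`,
#'   `reclassification` (NRI + IDI per pairing), `calibration`
#'   (Hosmer-Lemeshow per modified score) and `decision_curves`. When
#'   `config$out_dir` is set, each table is also written as TSV/JSON.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  cohort <- if (!is.null(config$baseline_path))
    read_cohort(config$baseline_path, config$inr_path)
  else generate_cohort(config$simulate)

  ttr <- ttr_cohort(cohort, threshold_pct = config$ttr_threshold)
  labile <- ttr$labile

  long <- score_cohort(cohort, labile_inr = labile,
                       scores = c(.base_scores, .modified_scores,
                                  "CHA2DS2VASC"))
  points <- .points_matrix(long, cohort$patients$patient_id)
  category <- .category_matrix(long, cohort$patients$patient_id)

  p <- cohort$patients
  outcome <- p$bled
  time <- p$followup_years

  rates <- rbind(
    major = crude_and_annualized_rates(cohort),
    intracranial = crude_and_annualized_rates(cohort, function(q)
      q$bled & q$bleed_site %in% "intracranial"),
    gastrointestinal = crude_and_annualized_rates(cohort, function(q)
      q$bled & q$bleed_site %in% "gastrointestinal"),
    fatal = crude_and_annualized_rates(cohort, function(q)
      q$bled & q$bleed_fatal %in% TRUE))

  evaluable <- c(.base_scores, .modified_scores)
  or_table <- do.call(rbind, lapply(evaluable, function(s) {
    hi <- category[, s] == "high_or_medium_high"
    t <- two_by_two(sum(hi & outcome), sum(hi & !outcome),
                    sum(!hi & outcome), sum(!hi & !outcome))
    o <- odds_ratio(t)
    data.frame(score = s, a = t$a, b = t$b, c = t$c, d = t$d,
               or = o$or_value, ci_low = o$ci_low, ci_high = o$ci_high,
               p = o$p_value, stringsAsFactors = FALSE)
  }))

  dist_tab <- score_distribution_table(
    long[long$score_name %in% evaluable, ],
    stats::setNames(outcome, p$patient_id))

  km <- list(); log_rank <- list(); cox <- list()
  for (s in evaluable) {
    hi <- category[, s] == "high_or_medium_high"
    km[[s]] <- list(low = kaplan_meier(time[!hi], outcome[!hi]),
                    high = kaplan_meier(time[hi], outcome[hi]))
    log_rank[[s]] <- log_rank_test(time, outcome, hi)
    cox[[s]] <- list(
      continuous = cox_univariate(time, outcome, points[, s]),
      categorical = cox_univariate(time, outcome, as.numeric(hi)))
  }

  c_indexes <- vapply(evaluable, function(s)
    c_index(points[, s], outcome), numeric(1))

  pairings <- c(lapply(setdiff(.base_scores, "HASBLED"), function(s)
    c("HASBLED", s)),
    lapply(.modified_scores, function(s) c(sub("_TTR$", "", s), s)))
  delong <- lapply(pairings, function(pr)
    delong_compare(points[, pr[1]], points[, pr[2]], outcome))
  names(delong) <- vapply(pairings, paste, character(1), collapse = "_vs_")

  prob <- lapply(evaluable, function(s)
    score_to_probability(points[, s], outcome))
  names(prob) <- evaluable
  reclass <- lapply(.modified_scores, function(s) {
    base <- sub("_TTR$", "", s)
    list(nri = nri(prob[[base]], prob[[s]], outcome),
         idi = idi(prob[[base]], prob[[s]], outcome))
  })
  names(reclass) <- paste0(sub("_TTR$", "", .modified_scores), "_vs_",
                           .modified_scores)

  calib <- lapply(.modified_scores, function(s)
    hosmer_lemeshow(prob[[s]], outcome))
  names(calib) <- .modified_scores

  dca <- decision_curves(prob, outcome)

  report <- structure(list(
    config = config, cohort = cohort, ttr = ttr, scores_long = long,
    points = points, category = category, rates = rates,
    or_table = or_table, distribution_table = dist_tab, km = km,
    log_rank = log_rank, cox = cox, c_indexes = c_indexes, delong = delong,
    reclassification = reclass, calibration = calib,
    decision_curves = dca), class = "evaluation_report")

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$cohort)
  cat(sprintf("  labile INR (TTR < %g%%): %.1f%% of patients\n",
              x$config$ttr_threshold, 100 * mean(x$ttr$labile)))
  cat(sprintf("  major bleeds: %d (%.1f%%, %.2f%%/year)\n",
              x$rates["major", "count"], x$rates["major", "crude_pct"],
              x$rates["major", "pct_per_year"]))
  cat("  c-indexes:\n")
  for (s in names(x$c_indexes))
    cat(sprintf("    %-18s %.3f\n", s, x$c_indexes[s]))
  invisible(x)
}

.points_matrix <- function(long, ids) {
  scores <- unique(long$score_name)
  m <- vapply(scores, function(s) {
    d <- long[long$score_name == s, ]
    d$points[match(ids, d$patient_id)]
  }, numeric(length(ids)))
  rownames(m) <- ids
  m
}

.category_matrix <- function(long, ids) {
  scores <- unique(long$score_name)
  m <- vapply(scores, function(s) {
    d <- long[long$score_name == s, ]
    d$category[match(ids, d$patient_id)]
  }, character(length(ids)))
  rownames(m) <- ids
  m
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  .write_tsv(report$ttr, f("ttr.tsv"))
  .write_tsv(report$scores_long, f("scores.tsv"))
  .write_tsv(cbind(event = rownames(report$rates),
                   as.data.frame(report$rates)), f("rates.tsv"))
  .write_tsv(report$or_table, f("odds_ratios.tsv"))
  .write_tsv(report$distribution_table, f("distribution.tsv"))
  .write_tsv(report$decision_curves, f("decision_curves.tsv"))
  .write_tsv(data.frame(score = names(report$c_indexes),
                        c_index = as.numeric(report$c_indexes)),
             f("c_indexes.tsv"))
  lr <- do.call(rbind, lapply(names(report$log_rank), function(s)
    data.frame(score = s, t(report$log_rank[[s]]))))
  .write_tsv(lr, f("log_rank.tsv"))
  cox_tab <- do.call(rbind, lapply(names(report$cox), function(s)
    do.call(rbind, lapply(c("continuous", "categorical"), function(k) {
      ft <- report$cox[[s]][[k]]
      data.frame(score = s, kind = k, hr = ft$hr, ci_low = ft$ci_low,
                 ci_high = ft$ci_high, p = ft$p_value,
                 converged = ft$converged)
    }))))
  .write_tsv(cox_tab, f("cox.tsv"))
  eval_tab <- do.call(rbind, lapply(names(report$delong), function(k) {
    d <- report$delong[[k]]
    data.frame(pairing = k, c_index_a = d$c_index_a, c_index_b = d$c_index_b,
               z = d$z_statistic, p = d$p_value)
  }))
  .write_tsv(eval_tab, f("delong.tsv"))
  rc <- do.call(rbind, lapply(names(report$reclassification), function(k) {
    r <- report$reclassification[[k]]
    data.frame(pairing = k, nri = r$nri$nri, nri_p = r$nri$p_value,
               idi = r$idi$idi, idi_p = r$idi$p_value)
  }))
  .write_tsv(rc, f("reclassification.tsv"))
  hl <- do.call(rbind, lapply(names(report$calibration), function(k) {
    h <- report$calibration[[k]]
    data.frame(score = k, hl_statistic = h$hl_statistic, df = h$df,
               p = h$p_value)
  }))
  .write_tsv(hl, f("hosmer_lemeshow.tsv"))
  jsonlite::write_json(
    list(seed = report$config$seed,
         ttr_threshold = report$config$ttr_threshold,
         n_patients = nrow(report$cohort$patients),
         package_version = as.character(utils::packageVersion("bleedrisk"))),
    f("run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
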