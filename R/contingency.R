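# 2x2 association statistics and event-rate summaries: odds ratios with
# Woolf (log-OR normal) confidence intervals, Pearson chi-squared for
# proportions, crude and annualized (person-time) event rates, and the
# events-by-score distribution table.

#' Construct a 2x2 table
#'
#' Layout: `a` exposed with event, `b` exposed without, `c` unexposed with
#' event, `d` unexposed without.
#'
#' @param a,b,c,d Non-negative counts; the total must be positive.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- as.numeric(c(a = a, b = b, c = c, d = d))
  names(cells) <- c("a", "b", "c", "d")
  if (any(is.na(cells)) || any(cells < 0))
    stop("all four cells must be non-negative counts", call. = FALSE)
  if (sum(cells) <= 0) stop("table total must be positive", call. = FALSE)
  structure(as.list(cells), class = "two_by_two")
}

.check_margins <- function(t) {
  if ((t$a + t$b) == 0 || (t$c + t$d) == 0 ||
      (t$a + t$c) == 0 || (t$b + t$d) == 0)
    stop("undefined: 2x2 table has a zero margin", call. = FALSE)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = ad/bc with the Woolf log-OR normal interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a Pearson
#' chi-squared p-value (no continuity correction). When any cell is zero
#' the Haldane-Anscombe 0.5 correction is applied to all cells for the OR
#' and CI, with a warning.
#'
#' @param t A [two_by_two()].
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return List `or_value`, `ci_low`, `ci_high`, `p_value`
#'   (class `or_result`).
#' @export
odds_ratio <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  .check_margins(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    warning("zero cell: applying Haldane-Anscombe 0.5 correction", call. = FALSE)
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  p <- chi_squared_proportions(t)["p_value"]
  structure(list(or_value = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p_value = unname(p)),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f), p = %.3g\n",
              x$or_value, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' No continuity correction, df = 1; equals the squared two-proportion z
#' statistic.
#'
#' @param t A [two_by_two()].
#' @return Named numeric `c(statistic, p_value)`.
#' @export
chi_squared_proportions <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  .check_margins(t)
  n <- t$a + t$b + t$c + t$d
  stat <- n * (t$a * t$d - t$b * t$c)^2 /
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d))
  c(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Crude and annualized event rates
#'
#' Counts patients matching a predicate, as a crude percentage of the
#' cohort and as percent per year of observed person-time
#' (`100 * count / sum(followup_years)`).
#'
#' @param cohort A `bleed_cohort`.
#' @param event_filter Function of the baseline data.frame returning a
#'   logical per patient (default: any major bleed).
#' @return Named numeric `c(count, crude_pct, pct_per_year)`.
#' @export
crude_and_annualized_rates <- function(cohort,
                                       event_filter = function(p) p$bled) {
  p <- if (inherits(cohort, "bleed_cohort")) cohort$patients else cohort
  if (nrow(p) == 0) stop("empty cohort", call. = FALSE)
  hit <- event_filter(p)
  stopifnot(length(hit) == nrow(p))
  count <- sum(hit, na.rm = TRUE)
  c(count = count,
    crude_pct = 100 * count / nrow(p),
    pct_per_year = if (count == 0) 0 else 100 * count / sum(p$followup_years))
}

#' Distribution of events by score value and category
#'
#' Tabulates event counts and percentages per score value (capped at
#' ">=5") and per risk category, one block per score -- the shape of a
#' published events-by-score table.
#'
#' @param score_results Tidy data.frame from [score_cohort()] (columns
#'   `patient_id`, `score_name`, `points`, `category`).
#' @param event_flags Named logical vector (names = patient ids) or a
#'   logical vector aligned with each score's patients.
#' @param cap Score values at or above this are pooled (default 5).
#' @return data.frame: `score_name`, `row` ("0".."4", ">=5", "low",
#'   "high_or_medium_high"), `n_events`, `pct_of_events`.
#' @export
score_distribution_table <- function(score_results, event_flags, cap = 5L) {
  stopifnot(all(c("score_name", "points", "category", "patient_id")
                %in% names(score_results)))
  out <- lapply(split(score_results, score_results$score_name), function(df) {
    ev <- if (!is.null(names(event_flags)))
      event_flags[df$patient_id] else event_flags
    if (length(ev) != nrow(df) || any(is.na(ev)))
      stop("event_flags misaligned with score_results", call. = FALSE)
    total <- sum(ev)
    vals <- pmin(df$points, cap)
    rows_val <- vapply(0:cap, function(v) sum(ev & vals == v), numeric(1))
    rows_cat <- vapply(c("low", "high_or_medium_high"),
                       function(k) sum(ev & df$category == k), numeric(1))
    lab <- c(as.character(0:(cap - 1)), paste0(">=", cap),
             "low", "high_or_medium_high")
    data.frame(score_name = df$score_name[1], row = lab,
               n_events = c(rows_val, rows_cat),
               pct_of_events = if (total > 0)
                 100 * c(rows_val, rows_cat) / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
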