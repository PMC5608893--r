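# Time in therapeutic range by Rosendaal linear interpolation. Between
# consecutive INR measurements the INR is assumed to change linearly by
# day; each inter-visit day is split into below/in/above range by the
# crossing times of the range limits on the linear segment. Long gaps
# contribute no time at all (neither numerator nor denominator).

# Vectorised segment engine over a long (patient_id, day, inr) table.
# Returns per-patient sums of in/below/above/total days plus PINRR counts.
.ttr_bulk <- function(inr, range_low, range_high, window_days, max_gap_days) {
  if (any(diff(inr$day)[inr$patient_id[-1] == inr$patient_id[-nrow(inr)]] <= 0))
    stop("INR days must be strictly increasing within a patient", call. = FALSE)

  ids <- unique(inr$patient_id)
  # observations inside the window (for PINRR and usable-segment counting)
  in_win <- inr$day <= window_days
  n_obs <- rowsum_safe(as.numeric(in_win), inr$patient_id, ids)
  n_in_range <- rowsum_safe(
    as.numeric(in_win & inr$inr >= range_low & inr$inr <= range_high),
    inr$patient_id, ids)

  n <- nrow(inr)
  same <- inr$patient_id[-1] == inr$patient_id[-n]
  d1 <- inr$day[-n][same];  d2 <- inr$day[-1][same]
  i1 <- inr$inr[-n][same];  i2 <- inr$inr[-1][same]
  pid <- inr$patient_id[-n][same]

  keep <- (d2 - d1) <= max_gap_days & d1 < window_days
  d1 <- d1[keep]; d2 <- d2[keep]; i1 <- i1[keep]; i2 <- i2[keep]
  pid <- pid[keep]

  # clip segments at the window end by interpolation
  over <- d2 > window_days
  if (any(over)) {
    frac <- (window_days - d1[over]) / (d2[over] - d1[over])
    i2[over] <- i1[over] + (i2[over] - i1[over]) * frac
    d2[over] <- window_days
  }
  total <- d2 - d1

  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  flat <- hi == lo
  frac_in <- frac_below <- frac_above <- numeric(length(total))
  if (any(flat)) {
    frac_in[flat] <- as.numeric(lo[flat] >= range_low & lo[flat] <= range_high)
    frac_below[flat] <- as.numeric(lo[flat] < range_low)
    frac_above[flat] <- as.numeric(lo[flat] > range_high)
  }
  sl <- !flat
  if (any(sl)) {
    span <- hi[sl] - lo[sl]
    frac_in[sl] <- pmax(0, pmin(hi[sl], range_high) - pmax(lo[sl], range_low)) / span
    frac_below[sl] <- pmax(0, pmin(hi[sl], range_low) - lo[sl]) / span
    frac_above[sl] <- pmax(0, hi[sl] - pmax(lo[sl], range_high)) / span
  }

  data.frame(
    patient_id = ids,
    days_in = rowsum_safe(frac_in * total, pid, ids),
    days_below = rowsum_safe(frac_below * total, pid, ids),
    days_above = rowsum_safe(frac_above * total, pid, ids),
    covered_days = rowsum_safe(total, pid, ids),
    n_observations = n_obs,
    n_in_range = n_in_range,
    stringsAsFactors = FALSE
  )
}

# rowsum() that returns 0 for absent groups, aligned to `levels`
rowsum_safe <- function(x, group, levels) {
  if (length(x) == 0) return(numeric(length(levels)))
  s <- rowsum(x, group)
  out <- as.numeric(s[match(levels, rownames(s)), 1])
  out[is.na(out)] <- 0
  out
}

.ttr_result <- function(row, threshold_pct) {
  if (row$n_observations < 2 || row$covered_days <= 0)
    stop("undefined TTR: fewer than 2 usable INR observations in the window",
         call. = FALSE)
  ttr <- 100 * row$days_in / row$covered_days
  structure(list(
    ttr_pct = ttr,
    below_pct = 100 * row$days_below / row$covered_days,
    above_pct = 100 * row$days_above / row$covered_days,
    pinrr_pct = 100 * row$n_in_range / row$n_observations,
    n_observations = as.integer(row$n_observations),
    covered_days = row$covered_days,
    labile = ttr < threshold_pct
  ), class = "ttr_result")
}

#' @export
print.ttr_result <- function(x, ...) {
  cat(sprintf("<ttr_result> TTR %.1f%% (below %.1f%%, above %.1f%%), PINRR %.1f%%, %d obs over %g days%s\n",
              x$ttr_pct, x$below_pct, x$above_pct, x$pinrr_pct,
              x$n_observations, x$covered_days,
              if (x$labile) " [labile]" else ""))
  invisible(x)
}

#' Rosendaal time in therapeutic range for one INR series
#'
#' Computes TTR over an observation window (default the first 183 days, the
#' conventional "6 months after entry") by linear interpolation between
#' consecutive INR measurements. Inter-visit gaps longer than
#' `max_gap_days` are excluded from both numerator and denominator; the
#' last segment is clipped at the window boundary by interpolation; time
#' after the last in-window observation contributes nothing. An INR exactly
#' at a range limit counts as in range.
#'
#' @param series data.frame with columns `day` (integer offsets, strictly
#'   increasing) and `inr`, or a two-column day/inr matrix-like object.
#' @param range_low,range_high Therapeutic limits (default 2.0-3.0).
#' @param window_days Observation window in days (default 183; `Inf` for
#'   the whole series).
#' @param max_gap_days Longest inter-visit gap still interpolated
#'   (default 56; `Inf` disables the cap).
#' @param threshold_pct Labile-INR threshold: TTR strictly below this is
#'   labile (default 65, the NICE good-control cut-off).
#' @return A `ttr_result`: `ttr_pct`, `below_pct`, `above_pct`,
#'   `pinrr_pct` (proportion of in-window INR values in range),
#'   `n_observations`, `covered_days`, `labile`.
#' @export
rosendaal_ttr <- function(series, range_low = 2.0, range_high = 3.0,
                          window_days = 183, max_gap_days = 56,
                          threshold_pct = 65) {
  series <- as.data.frame(series)
  if (!all(c("day", "inr") %in% names(series)))
    stop("series needs columns 'day' and 'inr'", call. = FALSE)
  if (nrow(series) < 2)
    stop("undefined TTR: fewer than 2 observations", call. = FALSE)
  df <- data.frame(patient_id = "p", day = as.numeric(series$day),
                   inr = as.numeric(series$inr), stringsAsFactors = FALSE)
  agg <- .ttr_bulk(df, range_low, range_high, window_days, max_gap_days)
  .ttr_result(agg[1, ], threshold_pct)
}

#' Per-patient TTR over a cohort
#'
#' Vectorised [rosendaal_ttr()] across every patient's INR series.
#'
#' @param cohort A `bleed_cohort` (or a long INR data.frame with
#'   `patient_id`, `day`, `inr`).
#' @inheritParams rosendaal_ttr
#' @param on_undefined "error" (default) to fail on any patient with fewer
#'   than 2 usable observations, or "na" to return NA rows for them.
#' @return data.frame keyed by `patient_id` with the `ttr_result` fields.
#' @export
ttr_cohort <- function(cohort, range_low = 2.0, range_high = 3.0,
                       window_days = 183, max_gap_days = 56,
                       threshold_pct = 65,
                       on_undefined = c("error", "na")) {
  on_undefined <- match.arg(on_undefined)
  inr <- if (inherits(cohort, "bleed_cohort")) cohort$inr else as.data.frame(cohort)
  inr <- inr[order(inr$patient_id, inr$day), , drop = FALSE]
  agg <- .ttr_bulk(inr, range_low, range_high, window_days, max_gap_days)
  undef <- agg$n_observations < 2 | agg$covered_days <= 0
  if (any(undef) && on_undefined == "error")
    stop("undefined TTR for patient(s) ",
         paste(utils::head(agg$patient_id[undef], 5), collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    patient_id = agg$patient_id,
    ttr_pct = ifelse(undef, NA_real_, 100 * agg$days_in / agg$covered_days),
    below_pct = ifelse(undef, NA_real_, 100 * agg$days_below / agg$covered_days),
    above_pct = ifelse(undef, NA_real_, 100 * agg$days_above / agg$covered_days),
    pinrr_pct = ifelse(agg$n_observations > 0,
                       100 * agg$n_in_range / agg$n_observations, NA_real_),
    n_observations = as.integer(agg$n_observations),
    covered_days = agg$covered_days,
    stringsAsFactors = FALSE
  )
  out$labile <- out$ttr_pct < threshold_pct
  if (inherits(cohort, "bleed_cohort"))  # preserve baseline patient order
    out <- out[match(cohort$patients$patient_id, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labile-INR flag from a TTR result
#'
#' Labile INR (poor anticoagulation control) is TTR strictly below the
#' threshold; a TTR of exactly 65% is not labile, since good control is
#' defined as TTR > 65%.
#'
#' @param ttr A `ttr_result`, or a numeric TTR percentage.
#' @param threshold_pct Control threshold in percent (default 65).
#' @return Logical flag.
#' @export
labile_flag <- function(ttr, threshold_pct = 65) {
  pct <- if (inherits(ttr, "ttr_result")) ttr$ttr_pct else as.numeric(ttr)
  pct < threshold_pct
}
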