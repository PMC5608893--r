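# Decision-curve analysis: net benefit of treating at a risk threshold,
# against treat-all and treat-none reference strategies.

#' Net benefit at one threshold
#'
#' Classifies a subject positive iff predicted probability >= threshold
#' (ties positive, for bit-exact reproducibility) and returns
#' `TP/N - (FP/N) * t / (1 - t)`.
#'
#' @param prob Predicted probabilities.
#' @param outcome Logical/0-1 events.
#' @param threshold Risk threshold in (0, 1).
#' @return Net benefit (real; never exceeds the event prevalence).
#' @export
net_benefit <- function(prob, outcome, threshold) {
  outcome <- as.logical(outcome)
  stopifnot(length(prob) == length(outcome), !any(is.na(outcome)))
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  n <- length(prob)
  pos <- prob >= threshold
  tp <- sum(pos & outcome)
  fp <- sum(pos & !outcome)
  tp / n - (fp / n) * threshold / (1 - threshold)
}

#' Decision curves over a threshold grid
#'
#' Net-benefit curves for each candidate model plus the treat-all and
#' treat-none references. Treat-none is identically 0; treat-all equals
#' `prevalence - (1 - prevalence) * t / (1 - t)`.
#'
#' @param models Named list of probability vectors (one per model).
#' @param outcome Logical/0-1 events.
#' @param thresholds Grid of thresholds (default 0.01 to 0.50 by 0.01;
#'   prophylaxis decisions beyond 50% risk are clinically meaningless).
#' @return Tidy data.frame: `model`, `threshold`, `net_benefit`.
#' @export
decision_curves <- function(models, outcome,
                            thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (!is.list(models) || length(models) == 0 || is.null(names(models)) ||
      any(names(models) == ""))
    stop("models must be a non-empty named list", call. = FALSE)
  outcome <- as.logical(outcome)
  prev <- mean(outcome)
  rows <- lapply(names(models), function(nm) {
    data.frame(model = nm, threshold = thresholds,
               net_benefit = vapply(thresholds, function(t)
                 net_benefit(models[[nm]], outcome, t), numeric(1)),
               stringsAsFactors = FALSE)
  })
  refs <- rbind(
    data.frame(model = "treat_all", threshold = thresholds,
               net_benefit = prev - (1 - prev) * thresholds / (1 - thresholds),
               stringsAsFactors = FALSE),
    data.frame(model = "treat_none", threshold = thresholds,
               net_benefit = 0, stringsAsFactors = FALSE)
  )
  out <- rbind(do.call(rbind, rows), refs)
  rownames(out) <- NULL
  out
}
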