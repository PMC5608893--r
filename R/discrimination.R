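# Discrimination, reclassification and calibration machinery: c-index
# (Mann-Whitney concordance), DeLong paired AUC comparison, logistic
# calibration of integer scores to event probabilities, Pencina NRI/IDI
# and the Hosmer-Lemeshow chi-squared.

.check_binary <- function(outcome) {
  outcome <- as.logical(outcome)
  if (any(is.na(outcome))) stop("outcome must be 0/1", call. = FALSE)
  if (!any(outcome) || all(outcome))
    stop("both outcome classes must be present", call. = FALSE)
  outcome
}

#' Concordance index (AUC for a binary outcome)
#'
#' Mann-Whitney estimate: the probability a random event subject scores
#' above a random non-event subject, counting ties as 1/2. Computed from
#' midranks, so invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores Numeric risk scores.
#' @param outcome Logical/0-1 events.
#' @return c-index in [0, 1].
#' @export
c_index <- function(scores, outcome) {
  outcome <- .check_binary(outcome)
  stopifnot(length(scores) == length(outcome))
  r <- rank(scores)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each event, the placement value
# against all non-events (and vice versa).
.delong_components <- function(scores, outcome) {
  sx <- scores[outcome]; sy <- scores[!outcome]
  v10 <- vapply(sx, function(s) mean((s > sy) + 0.5 * (s == sy)), numeric(1))
  v01 <- vapply(sy, function(s) mean((sx > s) + 0.5 * (sx == s)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong comparison of two correlated ROC curves
#'
#' Paired AUC difference test using the DeLong structural-component
#' covariance estimate and a two-sided z test. Antisymmetric: swapping the
#' two scores negates z.
#'
#' @param scores_a,scores_b Paired risk scores on the same subjects.
#' @param outcome Logical/0-1 events.
#' @return `roc_comparison` list: `c_index_a`, `c_index_b`, `var_diff`,
#'   `z_statistic`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, outcome) {
  outcome <- .check_binary(outcome)
  if (length(scores_a) != length(outcome) ||
      length(scores_b) != length(outcome))
    stop("scores must be paired with the outcome (equal lengths)",
         call. = FALSE)
  A <- .delong_components(scores_a, outcome)
  B <- .delong_components(scores_b, outcome)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  # covariance matrix of (AUC_a, AUC_b)
  s10 <- stats::cov(cbind(A$v10, B$v10))
  s01 <- stats::cov(cbind(A$v01, B$v01))
  S <- s10 / n1 + s01 / n0
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- A$auc - B$auc
  if (abs(diff) < 1e-15 && var_diff < 1e-15) {
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(c_index_a = A$auc, c_index_b = B$auc, var_diff = var_diff,
                 z_statistic = z, p_value = p),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("c-index %.3f vs %.3f, z = %.3f, p = %.3g\n",
              x$c_index_a, x$c_index_b, x$z_statistic, x$p_value))
  invisible(x)
}

#' Calibrate integer scores to event probabilities
#'
#' Univariate logistic regression of the outcome on the score points
#' (maximum likelihood); returns fitted event probabilities. This supplies
#' the probability scale needed by IDI, Hosmer-Lemeshow and decision-curve
#' analysis; rank-based statistics (c-index, DeLong) bypass it.
#'
#' @param scores Numeric scores.
#' @param outcome Logical/0-1 events.
#' @return Numeric vector of fitted probabilities, with the fitted
#'   `coefficients` as an attribute.
#' @export
score_to_probability <- function(scores, outcome) {
  outcome <- .check_binary(outcome)
  stopifnot(length(scores) == length(outcome))
  if (stats::var(scores) == 0) {
    p <- rep(mean(outcome), length(scores))
    attr(p, "coefficients") <- c(intercept = stats::qlogis(mean(outcome)),
                                 slope = 0)
    return(p)
  }
  fit <- stats::glm(outcome ~ scores, family = stats::binomial())
  if (!fit$converged || any(fit$fitted.values > 1 - 1e-10) &&
      any(fit$fitted.values < 1e-10))
    stop("logistic calibration failed (possible complete separation)",
         call. = FALSE)
  p <- as.numeric(fit$fitted.values)
  attr(p, "coefficients") <- stats::setNames(stats::coef(fit),
                                             c("intercept", "slope"))
  p
}

#' Net reclassification improvement (Pencina)
#'
#' Continuous mode (default): "up" is any increase of predicted
#' probability from old to new model, "down" any decrease. Two-category
#' mode: up/down means crossing `category_threshold`.
#' `nri = [P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)]`,
#' with the asymptotic z test of Pencina.
#'
#' @param prob_old,prob_new Predicted probabilities per subject.
#' @param outcome Logical/0-1 events.
#' @param mode "continuous" or "two_category".
#' @param category_threshold Probability cut-point for two_category mode.
#' @return `reclassification_result`: `nri`, `nri_events`,
#'   `nri_nonevents`, `z`, `p_value`.
#' @export
nri <- function(prob_old, prob_new, outcome,
                mode = c("continuous", "two_category"),
                category_threshold = NULL) {
  mode <- match.arg(mode)
  outcome <- .check_binary(outcome)
  stopifnot(length(prob_old) == length(outcome),
            length(prob_new) == length(outcome))
  if (mode == "continuous") {
    up <- prob_new > prob_old
    down <- prob_new < prob_old
  } else {
    if (is.null(category_threshold))
      stop("two_category mode needs category_threshold", call. = FALSE)
    old_hi <- prob_old >= category_threshold
    new_hi <- prob_new >= category_threshold
    up <- new_hi & !old_hi
    down <- !new_hi & old_hi
  }
  n_e <- sum(outcome); n_ne <- sum(!outcome)
  pu_e <- mean(up[outcome]);    pd_e <- mean(down[outcome])
  pu_ne <- mean(up[!outcome]);  pd_ne <- mean(down[!outcome])
  nri_e <- pu_e - pd_e
  nri_ne <- pd_ne - pu_ne
  v <- (pu_e + pd_e - (pu_e - pd_e)^2) / n_e +
       (pu_ne + pd_ne - (pd_ne - pu_ne)^2) / n_ne
  total <- nri_e + nri_ne
  z <- if (v > 0) total / sqrt(v) else 0
  structure(list(nri = total, nri_events = nri_e, nri_nonevents = nri_ne,
                 z = z, p_value = if (v > 0) 2 * stats::pnorm(-abs(z)) else 1),
            class = "reclassification_result")
}

#' Integrated discrimination improvement (Pencina)
#'
#' `idi = [mean(p_new|event) - mean(p_new|nonevent)] -
#'        [mean(p_old|event) - mean(p_old|nonevent)]`
#' -- the change in discrimination slope -- with the paired-difference
#' asymptotic z test.
#'
#' @inheritParams nri
#' @return `reclassification_result`: `idi`, `z`, `p_value`.
#' @export
idi <- function(prob_old, prob_new, outcome) {
  outcome <- .check_binary(outcome)
  stopifnot(length(prob_old) == length(outcome),
            length(prob_new) == length(outcome))
  d <- prob_new - prob_old
  d_e <- d[outcome]; d_ne <- d[!outcome]
  est <- mean(d_e) - mean(d_ne)
  se <- sqrt(stats::var(d_e) / length(d_e) + stats::var(d_ne) / length(d_ne))
  z <- if (se > 0) est / se else 0
  structure(list(idi = est, z = z,
                 p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1),
            class = "reclassification_result")
}

#' @export
print.reclassification_result <- function(x, ...) {
  if (!is.null(x$nri))
    cat(sprintf("NRI %.4f (events %.4f, nonevents %.4f), p = %.3g\n",
                x$nri, x$nri_events, x$nri_nonevents, x$p_value))
  else
    cat(sprintf("IDI %.4f, p = %.3g\n", x$idi, x$p_value))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by predicted probability into `bins` equal-count
#' groups (tied probabilities stay together, keeping the ranking
#' deterministic); the statistic is `sum (O - E)^2 / (E (1 - E / n_g))`
#' over bins with df = bins - 2. Bins whose expected count is zero are
#' merged with their neighbour with a warning.
#'
#' @param prob Predicted probabilities.
#' @param outcome Logical/0-1 events.
#' @param bins Number of risk groups (default 10).
#' @return `calibration_result`: `hl_statistic`, `df`, `p_value`,
#'   `bin_table` (per-bin n, observed, expected, mean probability).
#' @export
hosmer_lemeshow <- function(prob, outcome, bins = 10) {
  outcome <- .check_binary(outcome)
  stopifnot(length(prob) == length(outcome))
  n <- length(prob)
  ord <- order(prob)
  p_s <- prob[ord]; y_s <- outcome[ord]
  # equal-count cut points, then extend so equal values share a bin
  raw_bin <- ceiling(seq_len(n) / (n / bins))
  for (i in 2:n) if (p_s[i] == p_s[i - 1]) raw_bin[i] <- raw_bin[i - 1]
  bin_ids <- unique(raw_bin)
  tab <- data.frame(
    n = as.numeric(table(factor(raw_bin, levels = bin_ids))),
    observed = rowsum_safe(as.numeric(y_s), raw_bin, bin_ids),
    expected = rowsum_safe(p_s, raw_bin, bin_ids),
    mean_prob = rowsum_safe(p_s, raw_bin, bin_ids) /
      as.numeric(table(factor(raw_bin, levels = bin_ids)))
  )
  # merge zero-expectation bins into the next one
  while (any(tab$expected == 0) && nrow(tab) > 1) {
    warning("merging a zero-expected-count bin with its neighbour",
            call. = FALSE)
    i <- which(tab$expected == 0)[1]
    j <- if (i == nrow(tab)) i - 1 else i + 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, , drop = FALSE]
  }
  tab$mean_prob <- tab$expected / tab$n
  denom <- tab$expected * (1 - tab$expected / tab$n)
  denom[denom == 0] <- NA  # saturated bin (all expected): contributes 0/0
  terms <- (tab$observed - tab$expected)^2 / denom
  stat <- sum(terms, na.rm = TRUE)
  df <- nrow(tab) - 2
  structure(list(hl_statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
                 bin_table = tab),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi2 = %.3f on %d df, p = %.3g\n",
              x$hl_statistic, x$df, x$p_value))
  invisible(x)
}
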