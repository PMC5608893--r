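# c-index, DeLong, logistic calibration, NRI/IDI and Hosmer-Lemeshow.

test_that("c-index: separation, exchangeability, pair-enumeration oracle", {
  fx <- generate_worked_fixtures()$sep8
  expect_equal(c_index(fx$scores, fx$outcome), 1.0)
  expect_equal(c_index(-fx$scores, fx$outcome), 0.0)

  # brute-force enumeration over all event/non-event pairs
  pair_oracle <- function(s, y) {
    se <- s[y]; sn <- s[!y]
    mean(outer(se, sn, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    s <- sample(0:6, n, replace = TRUE)  # heavy ties
    expect_equal(c_index(s, y), pair_oracle(s, y))
  }
  # invariance under strictly increasing transforms
  y <- c(rep(TRUE, 10), rep(FALSE, 15))
  s <- rnorm(25)
  expect_equal(c_index(exp(s), y), c_index(s, y))
  expect_error(c_index(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("DeLong: self-comparison, reflection, antisymmetry", {
  fx <- generate_worked_fixtures()$delong30
  self <- delong_compare(fx$scores_a, fx$scores_a, fx$outcome)
  expect_equal(self$z_statistic, 0)
  expect_equal(self$p_value, 1)

  refl <- delong_compare(fx$scores_a, -fx$scores_a, fx$outcome)
  expect_equal(refl$c_index_a + refl$c_index_b, 1, tolerance = 1e-12)
  expect_gt(abs(refl$z_statistic), 0)

  ab <- delong_compare(fx$scores_a, fx$scores_b, fx$outcome)
  ba <- delong_compare(fx$scores_b, fx$scores_a, fx$outcome)
  expect_equal(ab$z_statistic, -ba$z_statistic, tolerance = 1e-12)
  expect_equal(ab$c_index_a, c_index(fx$scores_a, fx$outcome))
  expect_error(delong_compare(fx$scores_a[-1], fx$scores_b, fx$outcome),
               "paired")
})

test_that("DeLong variance agrees with a paired bootstrap (fixed fixture)", {
  fx <- generate_worked_fixtures()$delong30
  got <- delong_compare(fx$scores_a, fx$scores_b, fx$outcome)
  set.seed(32)
  n <- length(fx$outcome)
  reps <- 4000   # acceptance suite uses 20000; this is the fast check
  diffs <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    y <- fx$outcome[idx]
    if (!any(y) || all(y)) return(NA_real_)
    c_index(fx$scores_a[idx], y) - c_index(fx$scores_b[idx], y)
  }, numeric(1))
  expect_equal(got$var_diff, var(diffs, na.rm = TRUE), tolerance = 0.15)
})

test_that("logistic calibration: intercept-only, oracle fit, mean match", {
  y <- c(rep(TRUE, 4), rep(FALSE, 12))
  p <- score_to_probability(rep(3, 16), y)
  expect_equal(as.numeric(p), rep(0.25, 16))

  set.seed(33)
  s <- sample(0:5, 60, replace = TRUE)
  y <- runif(60) < plogis(-2 + 0.5 * s)
  if (!any(y)) y[1] <- TRUE
  if (all(y)) y[2] <- FALSE
  p <- score_to_probability(s, y)
  # fitted probabilities average to the observed prevalence
  expect_equal(mean(p), mean(y), tolerance = 1e-8)
  # grid-search maximum-likelihood oracle
  ll <- function(b0, b1) sum(stats::dbinom(y, 1, plogis(b0 + b1 * s),
                                           log = TRUE))
  co <- attr(p, "coefficients")
  grid0 <- seq(co["intercept"] - 0.02, co["intercept"] + 0.02, by = 1e-4)
  grid1 <- seq(co["slope"] - 0.02, co["slope"] + 0.02, by = 1e-4)
  best0 <- grid0[which.max(vapply(grid0, function(b) ll(b, co["slope"]),
                                  numeric(1)))]
  best1 <- grid1[which.max(vapply(grid1, function(b) ll(co["intercept"], b),
                                  numeric(1)))]
  expect_equal(unname(co["intercept"]), best0, tolerance = 1e-4)
  expect_equal(unname(co["slope"]), best1, tolerance = 1e-4)
})

test_that("NRI: null, maximal, worked 12-subject fixture, categorical mode", {
  fx <- generate_worked_fixtures()$nri12
  expect_equal(nri(fx$prob_old, fx$prob_old, fx$outcome)$nri, 0)

  # all events up, all nonevents down
  up <- ifelse(fx$outcome, fx$prob_old + 0.1, fx$prob_old - 0.05)
  expect_equal(nri(fx$prob_old, up, fx$outcome)$nri, 2)

  # hand count: events 3 up / 1 down; nonevents 3 up / 4 down / 1 tied
  r <- nri(fx$prob_old, fx$prob_new, fx$outcome)
  expect_equal(r$nri_events, 3/4 - 1/4)
  expect_equal(r$nri_nonevents, 4/8 - 3/8)
  expect_equal(r$nri, 0.625)
  expect_true(r$p_value > 0 && r$p_value <= 1)

  # two-category mode: crossing the 0.3 threshold
  r2 <- nri(fx$prob_old, fx$prob_new, fx$outcome, mode = "two_category",
            category_threshold = 0.3)
  # events: old >= .3 for subjects 3,4; new >= .3 for 3,4 -> one up (subj 2? no)
  # recompute by hand: old_hi = (.1,.2,.3,.4) >= .3 -> F,F,T,T
  #                    new_hi = (.2,.1,.4,.5) >= .3 -> F,F,T,T  => no moves
  expect_equal(r2$nri_events, 0)
  # nonevents: old_hi = F F F F T T T T ; new_hi = F F F F F T T T
  # -> one down, zero up => nri_nonevents = 1/8
  expect_equal(r2$nri_nonevents, 1/8)
  expect_error(nri(fx$prob_old, fx$prob_new, rep(TRUE, 12)), "both outcome")
})

test_that("IDI: null, arithmetic oracle, discrimination-slope identity", {
  fx <- generate_worked_fixtures()$nri12
  expect_equal(idi(fx$prob_old, fx$prob_old, fx$outcome)$idi, 0)

  r <- idi(fx$prob_old, fx$prob_new, fx$outcome)
  slope <- function(p) mean(p[fx$outcome]) - mean(p[!fx$outcome])
  expect_equal(r$idi, slope(fx$prob_new) - slope(fx$prob_old))

  # hand arithmetic on the fixture
  d_e <- mean(c(.2, .1, .4, .5)) - mean(c(.1, .2, .3, .4))
  d_ne <- mean(c(.05, .15, .1, .2, .25, .35, .3, .5)) -
    mean(c(.1, .1, .2, .2, .3, .3, .4, .4))
  expect_equal(r$idi, d_e - d_ne)
})

test_that("IDI detects a truly informative added component", {
  set.seed(34)
  n <- 2000
  base <- sample(0:5, n, replace = TRUE)
  extra <- rbinom(n, 1, 0.25)
  y <- runif(n) < plogis(-3 + 0.4 * base + 0.8 * extra)
  p_old <- score_to_probability(base, y)
  p_new <- score_to_probability(base + extra, y)
  r <- idi(p_old, p_new, y)
  expect_gt(r$idi, 0)
  expect_lt(r$p_value, 0.05)
})

test_that("Hosmer-Lemeshow: perfect calibration, manual bin oracle", {
  # observed frequencies exactly equal to the bin probabilities
  prob <- rep(c(0.2, 0.5), each = 10)
  outcome <- c(rep(c(TRUE, FALSE), c(2, 8)), rep(c(TRUE, FALSE), c(5, 5)))
  r <- hosmer_lemeshow(prob, outcome, bins = 2)
  expect_equal(r$hl_statistic, 0)

  # 20-subject fixture, hand-computed bin table with 4 bins of 5
  set.seed(35)
  prob <- round(seq(0.05, 0.62, length.out = 20), 3)
  outcome <- runif(20) < prob
  if (!any(outcome)) outcome[20] <- TRUE
  if (all(outcome)) outcome[1] <- FALSE
  r <- hosmer_lemeshow(prob, outcome, bins = 4)
  bin <- rep(1:4, each = 5)
  O <- tapply(outcome, bin, sum); E <- tapply(prob, bin, sum)
  ng <- tapply(prob, bin, length)
  manual <- sum((O - E)^2 / (E * (1 - E / ng)))
  expect_equal(r$hl_statistic, manual, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # ties at a bin edge stay together
  p2 <- c(rep(0.3, 12), rep(0.6, 8))
  r2 <- hosmer_lemeshow(p2, c(rbinom(12, 1, 0.3), rbinom(8, 1, 0.6)) == 1,
                        bins = 4)
  expect_equal(nrow(r2$bin_table), 2)
})
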