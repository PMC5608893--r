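# Kaplan-Meier, log-rank and Cox partial-likelihood fits, each checked
# against hand-computed oracles and (where available) the survival package.

test_that("Kaplan-Meier matches the hand-computed product limit", {
  # no events: flat at 1
  km <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km$survival, rep(1, 3))
  # one event among four at t = 1
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_equal(km$survival[1], 0.75)
  # 6-subject worked set with censoring
  fx <- generate_worked_fixtures()$km6
  km <- kaplan_meier(fx$time, fx$event)
  expect_equal(km$survival, c(5/6, 5/6, 5/8, 5/12, 5/12, 0))
  expect_equal(km$n_risk, 6:1)
  # with no censoring KM equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  km <- kaplan_meier(tt, rep(1, 5))
  expect_equal(km$survival,
               vapply(km$time, function(t) mean(tt > t), numeric(1)))
})

test_that("Kaplan-Meier agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(21)
  time <- rexp(60, 0.3); event <- rbinom(60, 1, 0.6)
  km <- kaplan_meier(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km$survival[km$n_event > 0],
               sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("log-rank statistic matches a manual O-E oracle and survdiff", {
  # manual oracle: explicit loop over event times, group 1 vs 2
  manual_logrank <- function(time, event, g) {
    O <- E <- V <- 0
    for (t in sort(unique(time[event == 1]))) {
      n <- sum(time >= t); n1 <- sum(time >= t & g == 1)
      d <- sum(event == 1 & time == t)
      d1 <- sum(event == 1 & time == t & g == 1)
      if (n <= 1) next
      O <- O + d1; E <- E + d * n1 / n
      V <- V + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
    }
    (O - E)^2 / V
  }
  set.seed(22)
  time <- c(rexp(30, 0.2), rexp(30, 0.5))
  event <- rbinom(60, 1, 0.7)
  g <- rep(1:2, each = 30)
  got <- log_rank_test(time, event, g)
  expect_equal(unname(got["statistic"]), manual_logrank(time, event, g),
               tolerance = 1e-10)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  expect_equal(unname(got["statistic"]), sd$chisq, tolerance = 1e-8)
})

test_that("log-rank: symmetry null, time-rescaling invariance, 3 groups", {
  set.seed(23)
  time <- rexp(40, 0.3); event <- rbinom(40, 1, 0.8)
  # two interleaved copies of the same data: statistic 0
  got <- log_rank_test(rep(time, 2), rep(event, 2), rep(1:2, each = 40))
  expect_equal(unname(got["statistic"]), 0, tolerance = 1e-12)
  # common rescaling of time changes nothing
  g <- rep(1:2, 20)
  a <- log_rank_test(time, event, g)
  b <- log_rank_test(time * 7.3, event, g)
  expect_equal(a, b, tolerance = 1e-12)
  # simulated 3x rate ratio is detected decisively
  set.seed(24)
  t2 <- c(rexp(500, 0.1), rexp(500, 0.3))
  cens <- pmin(t2, 8)
  got <- log_rank_test(cens, as.numeric(t2 < 8), rep(1:2, each = 500))
  expect_lt(unname(got["p_value"]), 0.001)
  skip_if_not_installed("survival")
  g3 <- sample(1:3, 40, replace = TRUE)
  g3[1:3] <- 1:3
  mine <- log_rank_test(time, event, g3)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g3)
  expect_equal(unname(mine["statistic"]), sd$chisq, tolerance = 1e-8)
  expect_equal(unname(mine["df"]), 2)
})

test_that("Cox beta matches the grid-search partial-likelihood oracle", {
  fx <- generate_worked_fixtures()$cox5
  fit <- cox_univariate(fx$time, fx$event, fx$x)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, function(b)
    bleedrisk:::cox_partial_loglik(fx$time, fx$event, fx$x, b), numeric(1))
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("Cox agrees with survival::coxph under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(25)
  n <- 120
  x <- rnorm(n)
  time <- round(rexp(n, exp(0.5 * x) * 0.3), 1) + 0.1  # forces ties
  event <- rbinom(n, 1, 0.7)
  for (ties in c("breslow", "efron")) {
    mine <- cox_univariate(time, event, x, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("Cox null case: permuted covariate gives HR near 1", {
  set.seed(26)
  n <- 2000
  x <- sample(rep(0:4, 400))
  time <- rexp(n, 0.1); event <- as.numeric(time < 6); time <- pmin(time, 6)
  fit <- cox_univariate(time, event, x)
  expect_true(fit$ci_low < 1 && 1 < fit$ci_high)
  expect_equal(fit$hr, 1, tolerance = 0.1)
})

test_that("score test at beta = 0 matches the log-rank statistic", {
  # classical identity for a binary covariate without ties
  set.seed(27)
  time <- rexp(50); event <- rbinom(50, 1, 0.7); x <- rbinom(50, 1, 0.5)
  # analytic score and information at beta = 0, by explicit risk-set loops
  U <- I <- 0
  for (i in which(event == 1)) {
    rs <- x[time >= time[i]]
    U <- U + x[i] - mean(rs)
    I <- I + mean(rs^2) - mean(rs)^2
  }
  lr <- log_rank_test(time, event, x)
  # without tied event times the identity is exact: the log-rank tie factor
  # (n-d)/(n-1) is 1 when every d = 1
  expect_equal(U^2 / I, unname(lr["statistic"]), tolerance = 1e-10)
  # and the score from the fitted path matches the analytic one
  eps <- 1e-5
  U_num <- (bleedrisk:::cox_partial_loglik(time, event, x, eps) -
              bleedrisk:::cox_partial_loglik(time, event, x, -eps)) / (2 * eps)
  expect_equal(U_num, U, tolerance = 1e-6)
})

test_that("monotone likelihood is flagged, not reported as a number", {
  # perfect risk-order separation: higher x always bleeds earlier
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- c(5, 4, 3, 0, 0, 0)
  fit <- cox_univariate(time, event, x)
  expect_false(fit$converged)
  expect_true(is.na(fit$hr))
})

test_that("degenerate inputs error cleanly", {
  expect_error(cox_univariate(c(1, 2), c(0, 0), c(0, 1)), "no events")
  expect_error(cox_univariate(c(1, 2), c(1, 0), c(1, 1)), "vary")
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(log_rank_test(c(1, 2), c(1, 1), c(1, 1)), "2 groups")
})
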