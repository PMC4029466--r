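test_that("binomial part recovers the closed-form 2x2 log odds ratio", {
  fit <- fit_binomial_part(fixture_2x2())
  # pre: 2 of 4 entry acquirers; post: 3 of 4 -> OR = (3/1)/(2/2) = 3
  expect_equal(unname(fit$coefficients["x"]), log(3), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["intercept"]), log(1),
               tolerance = 1e-6)
  expect_true(fit$converged && fit$identifiable)
  expect_gte(fit$lr_stat, 0)
  expect_identical(fit$n, 8L)
})

test_that("an entry exactly at t0 counts as post-intervention", {
  des <- toy_design()
  # post group consists solely of entries at exactly 2004
  d <- c(rep(2000, 4), rep(2004, 4))
  y <- c(1, 1, 0, 0, 1, 1, 1, 0)
  dat <- make_subjects(d, y, ifelse(y == 1, 0, des$tau - d), y)
  fit <- fit_binomial_part(dat)
  expect_equal(unname(fit$coefficients["x"]), log(3), tolerance = 1e-6)
})

test_that("degenerate binomial inputs are flagged, not fatal", {
  des <- toy_design()
  # all y identical -> non-identifiable
  dat <- make_subjects(c(2000, 2006), c(1, 1), c(0, 0), c(1, 1))
  fit <- fit_binomial_part(dat)
  expect_false(fit$identifiable)
  expect_match(fit$message, "non-identifiable")
  expect_true(is.na(fit$lr_stat))

  # log link with fitted probabilities near 1: honest non-convergence
  d <- c(seq(1995, 2003, length.out = 40),
         seq(2004.1, 2008.5, length.out = 40))
  y <- rep(1, 80); y[c(5, 15, 45, 55)] <- 0
  dat <- make_subjects(d, y, ifelse(y == 1, 0, des$tau - d), y)
  fit_log <- expect_no_error(fit_binomial_part(dat, link = "log"))
  expect_false(fit_log$converged)
  expect_false(is.null(fit_log$message))
  # the logit fit of the same data is fine
  expect_true(fit_binomial_part(dat, link = "logit")$converged)
})

test_that("Cox partial-likelihood estimate matches the brute-force oracle", {
  dat <- fixture_cox_toy()
  ep <- split_episodes(dat)
  fit <- fit_cox_part(dat, ties = "breslow")
  oracle <- gamma_grid_oracle(ep)
  expect_equal(fit$gamma, oracle, tolerance = 1e-4)
  # sanity: the oracle maximum really beats nearby values
  expect_gt(pll_breslow(oracle, ep), pll_breslow(oracle + 0.05, ep))
  expect_gt(pll_breslow(oracle, ep), pll_breslow(oracle - 0.05, ep))
  # distinct event times: Efron and Breslow coincide
  expect_equal(fit_cox_part(dat, ties = "efron")$gamma, fit$gamma,
               tolerance = 1e-8)
  # the reported partial log-likelihood agrees with the oracle's value
  expect_equal(fit$pll, pll_breslow(fit$gamma, ep), tolerance = 1e-6)
})

test_that("Cox part flags non-identifiability instead of crashing", {
  # every career starts after t0: z = 1 everywhere, no contrast
  dat <- make_subjects(c(2005, 2006, 2007), rep(0, 3), c(2, 1, 0.5),
                       c(1, 1, 1))
  fit <- fit_cox_part(dat)
  expect_false(fit$identifiable)
  expect_match(fit$message, "constant")
  # no y = 0 subjects at all: binomial-only analysis
  dat2 <- make_subjects(c(2000, 2006), c(1, 1), c(0, 0), c(1, 1))
  fit2 <- fit_cox_part(dat2)
  expect_false(fit2$identifiable)
  expect_identical(fit2$n_events, 0L)
  # no events (all censored)
  dat3 <- make_subjects(c(2000, 2006), c(0, 0), c(9, 3), c(0, 0))
  expect_false(fit_cox_part(dat3)$identifiable)
})

test_that("combined test adds components, df 2, p = exp(-stat/2)", {
  dat <- simulate_survey(scenario_from_levels("Low", "High"), seed = 2)
  bin <- fit_binomial_part(dat)
  cox <- fit_cox_part(dat)
  for (m in c("lr", "wald")) {
    tst <- combined_change_test(bin, cox, method = m)
    expect_identical(tst$df, 2L)
    expect_equal(tst$statistic, sum(tst$components))
    expect_equal(tst$p_value, exp(-tst$statistic / 2))
    expect_gte(tst$statistic, 0)
  }
  # chi-squared(2) anchor points (to printed precision)
  expect_equal(round(exp(-5.991 / 2), 3), 0.050)
  expect_equal(round(stats::pchisq(11.41, 2, lower.tail = FALSE), 4),
               0.0033)
})

test_that("one non-identifiable part downgrades to a flagged 1-df test", {
  # all y = 0: the Cox part is informative, the binomial part is not
  dat <- fixture_cox_toy()
  bin <- fit_binomial_part(dat)
  cox <- fit_cox_part(dat)
  expect_false(bin$identifiable)
  expect_true(cox$identifiable)
  tst <- combined_change_test(bin, cox)
  expect_true(tst$downgraded)
  expect_identical(tst$df, 1L)
  expect_true(is.na(tst$components["binomial"]))
  expect_equal(tst$statistic, cox$lr_stat)
  # both parts missing is an error
  expect_error(combined_change_test(
    structure(list(identifiable = FALSE, converged = FALSE),
              class = "binomial_part_fit"),
    structure(list(identifiable = FALSE, converged = FALSE),
              class = "cox_part_fit")), "both parts")
})

test_that("clustered robust Q has its closed form and chi-squared(2) p", {
  # beta1 = 0, gamma = 0 -> Q = 0, p = 1
  tst0 <- clustered_robust_test(fake_binfit(0, 0.3), fake_coxfit(0, 0.2))
  expect_equal(tst0$statistic, 0)
  expect_equal(tst0$p_value, 1)
  # beta1 = 1 with Vr = 0.25, gamma = 0 -> Q = 4, p = exp(-2)
  tst <- clustered_robust_test(fake_binfit(1, v_model = 0.1,
                                           v_robust = 0.25),
                               fake_coxfit(0, 0.2))
  expect_equal(tst$statistic, 4)
  expect_equal(tst$p_value, exp(-2))
  expect_identical(tst$method, "robust-Wald")
  # order of the two components is immaterial
  expect_equal(tst$statistic,
               clustered_robust_test(fake_binfit(0, 0.2),
                                     fake_coxfit(1, 0.1, 0.25))$statistic)
  # refusing to run without robust variances
  bare <- fake_binfit(1, 0.1)
  bare$cov_robust <- NULL
  expect_error(clustered_robust_test(bare, fake_coxfit(0, 0.2)),
               "cluster_robust")
})

test_that("subject-level sandwich agrees with model-based variances on independent data", {
  dat <- simulate_survey(scenario_from_levels("Medium", "High"), seed = 9)
  dat$cluster <- as.character(dat$id)  # every subject its own cluster
  bin <- fit_binomial_part(dat, cluster_robust = TRUE)
  cox <- fit_cox_part(dat, cluster_robust = TRUE)
  expect_equal(bin$cov_robust["x", "x"], bin$cov_model["x", "x"],
               tolerance = 0.15)
  expect_equal(cox$cov_robust["z", "z"], cox$cov_model["z", "z"],
               tolerance = 0.15)
  q <- clustered_robust_test(bin, cox)
  w <- combined_change_test(bin, cox, method = "wald")
  expect_equal(q$statistic, w$statistic, tolerance = 0.2)
})

test_that("single-Cox approximation is exact without entry acquirers and rank-invariant in epsilon", {
  dat <- fixture_cox_toy()      # all y = 0
  expect_equal(fit_single_cox_approx(dat)$gamma, fit_cox_part(dat)$gamma,
               tolerance = 1e-10)
  # with entry acquirers: halving epsilon preserves the event ordering,
  # hence the partial-likelihood estimate
  dat2 <- simulate_survey(scenario_from_levels("Medium", "Medium"),
                          seed = 10)
  eps <- 1 / 365.25
  f1 <- fit_single_cox_approx(dat2, epsilon = eps)
  f2 <- fit_single_cox_approx(dat2, epsilon = eps / 2)
  expect_identical(f1$approximation, "single-cox")
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-8)
  expect_identical(f1$n, nrow(dat2))
  # oversized epsilon distorts the ordering and warns
  expect_warning(fit_single_cox_approx(dat, epsilon = 5), "ordering")
})

test_that("calendar-year episode splitting yields year-constant intervals", {
  dat <- fixture_cox_toy()
  fit <- fit_cox_part(dat, calendar_year = TRUE,
                      extra_covariates = "year_c")
  ep <- fit$episodes
  d_of <- setNames(dat$d, as.character(dat$id))
  cal <- d_of[as.character(ep$id)] + ep$start
  # covariate is the calendar year at interval start, centered at t0
  expect_equal(ep$year_c, unname(floor(cal) - 2004))
  # no interval crosses a year boundary
  expect_true(all(floor(cal + (ep$stop - ep$start) - 1e-9) == floor(cal)))
  # tiling and event count still exact
  len <- tapply(ep$stop - ep$start, as.character(ep$id), sum)
  expect_equal(as.vector(len[as.character(dat$id)]), dat$c_tilde)
  expect_equal(sum(ep$event), sum(dat$delta))
  expect_true(all(c("z", "year_c") %in% names(fit$coefficients)))
})
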