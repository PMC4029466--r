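test_that("build_panel follows the January-1 evaluation rule", {
  des <- toy_design()
  # entry acquirer: rows from the first January 1 after entry, all 1
  p <- build_panel(make_subjects(2002.5, 1, 0, 1), year_grid = 2000:2008)
  expect_equal(p$year, 2003:2008)
  expect_true(all(p$response == 1))
  # hand enumeration: change at 2001.2 + 4.0 = 2005.2
  p2 <- build_panel(make_subjects(2001.2, 0, 4.0, 1),
                    year_grid = 2000:2008)
  expect_equal(p2$year, 2002:2008)
  expect_equal(p2$response, c(0L, 0L, 0L, 0L, 1L, 1L, 1L))
  # entry after the last grid year: no rows
  p3 <- build_panel(make_subjects(2008.9, 0, 0.1, 0),
                    year_grid = 2000:2008)
  expect_identical(nrow(p3), 0L)
  # grid guards
  expect_error(build_panel(make_subjects(2000, 1, 0, 1),
                           year_grid = 2000:2010), "beyond")
  expect_error(build_panel(make_subjects(2000, 1, 0, 1),
                           year_grid = 2005), ">= 2 years")
})

test_that("response is monotone within subject", {
  dat <- simulate_survey(scenario_from_levels("Medium", "High"), seed = 6)
  p <- build_panel(dat)
  mono <- tapply(p$response, as.character(p$id),
                 function(r) all(diff(r) >= 0))
  expect_true(all(mono))
})

test_that("identity-link coefficients are exactly the raw yearly proportions", {
  dat <- simulate_survey(scenario_from_levels("Low", "Medium"), seed = 7)
  p <- build_panel(dat)
  gf <- fit_yearly_rates_gee(p, "identity")
  raw <- tapply(p$response, p$year, mean)
  expect_equal(unname(gf$year_coefficients),
               as.vector(raw[as.character(gf$year_grid)]))
  # and they agree with the crude rate curve at the same grid points
  rc <- crude_rate_curve(dat, gf$year_grid)
  expect_equal(unname(gf$year_coefficients), rc$r_t)
  # logit link: same proportions on the logit scale
  gl <- fit_yearly_rates_gee(p, "logit")
  expect_equal(unname(gl$year_coefficients),
               as.vector(stats::qlogis(raw[as.character(gf$year_grid)])))
})

test_that("sandwich covariance matches a direct estimating-equation calculation", {
  dat <- simulate_survey(scenario_from_levels("Medium", "Medium"), seed = 8)
  p <- build_panel(dat)
  gf <- fit_yearly_rates_gee(p, "identity")
  # independent oracle: loop over subjects, stack scores
  yrs <- gf$year_grid
  p_y <- unname(gf$year_coefficients)
  v_y <- p_y * (1 - p_y)
  A <- diag(as.vector(table(factor(p$year, levels = yrs))) / v_y)
  U <- matrix(0, length(unique(p$id)), length(yrs))
  for (k in seq_along(unique(p$id))) {
    rows <- p[p$id == unique(p$id)[k], ]
    for (j in seq_len(nrow(rows))) {
      jj <- match(rows$year[j], yrs)
      U[k, jj] <- U[k, jj] + (rows$response[j] - p_y[jj]) / v_y[jj]
    }
  }
  V <- solve(A) %*% crossprod(U) %*% solve(A)
  expect_equal(unname(gf$cov_robust), unname(V), tolerance = 1e-10)
})

test_that("logit link with a saturated year cell is flagged NA, not an error", {
  des <- toy_design()
  # two subjects acquiring at entry in 2000: every panel response is 1
  dat <- make_subjects(c(2000.5, 2000.7), c(1, 1), c(0, 0), c(1, 1))
  p <- build_panel(dat, year_grid = 2001:2008)
  gf <- fit_yearly_rates_gee(p, "logit")
  expect_false(gf$converged)
  ct <- average_slope_contrast_test(gf, des, 2001:2008)
  expect_true(is.na(ct$p_value))
  # identity link on the same panel is estimable but rank-checked
  dat1 <- make_subjects(2000.5, 0, 8.5, 0)
  gf1 <- fit_yearly_rates_gee(build_panel(dat1, year_grid = 2001:2008),
                              "identity")
  expect_true(gf1$rank_deficient)
  expect_false(gf1$converged)
})

test_that("average-slope contrast reproduces hand arithmetic", {
  mu <- c(0.1, 0.2, 0.3, 0.3, 0.5, 0.7, 0.9)
  yrs <- 2001:2007
  gf <- fake_geefit(mu, yrs, sigma = 0.01 * diag(7))
  ct <- average_slope_contrast_test(gf, study_design(2004, 2009), yrs)
  expect_equal(ct$slope_pre, (0.3 - 0.1) / 3)
  expect_equal(ct$slope_post, (0.9 - 0.3) / 3)
  expect_equal(ct$diff, 0.2 - 0.2 / 3)
  cvec <- c(1 / 3, 0, 0, -2 / 3, 0, 0, 1 / 3)
  expect_equal(ct$se_diff, sqrt(0.01 * sum(cvec^2)))
  expect_equal(ct$p_value, 2 * pnorm(-abs(ct$diff / ct$se_diff)))
  # collinear coefficients: diff exactly 0, p = 1
  ct0 <- average_slope_contrast_test(
    fake_geefit(seq(0.1, 0.7, 0.1), yrs), study_design(2004, 2009), yrs)
  expect_equal(ct0$diff, 0)
  expect_equal(ct0$p_value, 1)
  # shifting every coefficient leaves the contrast unchanged
  ct_shift <- average_slope_contrast_test(
    fake_geefit(mu + 0.05, yrs, 0.01 * diag(7)),
    study_design(2004, 2009), yrs)
  expect_equal(ct_shift$diff, ct$diff)
  expect_equal(ct_shift$se_diff, ct$se_diff)
  # t0 must be interior
  expect_error(average_slope_contrast_test(gf, study_design(2007, 2009),
                                           yrs), "interior")
})

test_that("ceiling artifact: high pre-t0 rates bound the post slope", {
  # pre slope 0.1/year reaching 0.9 at t0; even the best possible post
  # path cannot match it
  mu <- c(0.6, 0.7, 0.8, 0.9, 0.925, 0.95, 0.975, 1.0)
  yrs <- 2001:2008
  ct <- average_slope_contrast_test(fake_geefit(mu, yrs),
                                    study_design(2004, 2009), yrs)
  expect_equal(ct$slope_post, (1 - 0.9) / 4)
  expect_lt(ct$diff, 0)
})
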