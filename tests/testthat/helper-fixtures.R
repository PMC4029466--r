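# shared fixtures and independent oracles, built in code

toy_design <- function() study_design(t0 = 2004, tau = 2009)

make_subjects <- function(d, y, c_tilde, delta, design = toy_design(),
                          ...) {
  validate_dataset(data.frame(d = d, y = y, c_tilde = c_tilde,
                              delta = delta, ...), design)
}

# saturated 2x2 binomial fixture: 2/4 entry acquirers pre-t0, 3/4 post;
# log odds ratio log((3/1)/(2/2)) = log 3
fixture_2x2 <- function(design = toy_design()) {
  d <- c(rep(2000, 4), rep(2006, 4))
  y <- c(1, 1, 0, 0, 1, 1, 1, 0)
  ct <- ifelse(y == 1, 0, design$tau - d)
  make_subjects(d, y, ct, delta = y, design = design)
}

# small all-positive-duration Cox fixture spanning the change point,
# distinct event times (Efron = Breslow)
fixture_cox_toy <- function(design = toy_design()) {
  make_subjects(d = c(2000, 2001, 2005, 1999, 2002, 2003),
                y = rep(0, 6),
                c_tilde = c(7, 2, 3, 10, 4.5, 2.5),
                delta = c(1, 1, 1, 0, 1, 1),
                design = design)
}

# independent Breslow partial log-likelihood oracle on episode rows:
# risk set recomputed from scratch at every event time
pll_breslow <- function(gamma, ep) {
  ev <- ep[ep$event == 1, , drop = FALSE]
  sum(vapply(seq_len(nrow(ev)), function(k) {
    t <- ev$stop[k]
    risk <- ep[ep$start < t & ep$stop >= t, , drop = FALSE]
    gamma * ev$z[k] - log(sum(exp(gamma * risk$z)))
  }, numeric(1)))
}

# brute-force maximizer of the oracle partial likelihood
gamma_grid_oracle <- function(ep, interval = c(-5, 5)) {
  stats::optimize(function(g) pll_breslow(g, ep), interval,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# closed-form survival of the piecewise-exponential duration for entry
# time d: hazard h1 while calendar < t0, h2 after
piecewise_surv <- function(c, d, h1, h2, t0) {
  sstar <- pmax(t0 - d, 0)
  exp(-(h1 * pmin(c, sstar) + h2 * pmax(c - sstar, 0)))
}

# fake fitted parts with prescribed estimates/variances, for closed-form
# checks of the combined statistics
fake_binfit <- function(beta1, v_model, v_robust = v_model) {
  structure(list(identifiable = TRUE, converged = TRUE,
                 coefficients = c(intercept = 0, x = beta1),
                 cov_model = matrix(c(1, 0, 0, v_model), 2, 2,
                                    dimnames = rep(list(c("intercept", "x")), 2)),
                 cov_robust = matrix(c(1, 0, 0, v_robust), 2, 2,
                                     dimnames = rep(list(c("intercept", "x")), 2)),
                 lr_stat = NA_real_),
            class = "binomial_part_fit")
}

fake_coxfit <- function(gamma, v_model, v_robust = v_model) {
  structure(list(identifiable = TRUE, converged = TRUE,
                 gamma = gamma,
                 cov_model = matrix(v_model, 1, 1,
                                    dimnames = list("z", "z")),
                 cov_robust = matrix(v_robust, 1, 1,
                                     dimnames = list("z", "z")),
                 lr_stat = NA_real_),
            class = "cox_part_fit")
}

fake_geefit <- function(mu, years, sigma = diag(length(mu))) {
  yrs <- as.character(years)
  dimnames(sigma) <- list(yrs, yrs)
  structure(list(link = "identity", year_grid = years,
                 year_coefficients = stats::setNames(mu, yrs),
                 cov_robust = sigma, converged = TRUE,
                 rank_deficient = FALSE),
            class = "gee_fit")
}
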