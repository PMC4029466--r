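#' Yearly panel for the GEE comparator
#'
#' Expands each subject into one row per calendar year of the grid
#' (evaluated at January 1): subject i contributes a row for year y iff
#' her career started before y (\code{d < y}); the response is 1 iff the
#' status was acquired by January 1 of year y, i.e. \code{y_i = 1} or
#' \code{delta = 1 and d + c_tilde <= y}.  The response is non-decreasing
#' within subject (the status change is permanent).
#'
#' @param dataset a validated \code{subject_data} object.
#' @param design optional [study_design()]; defaults to the attached one.
#' @param year_grid integer years, e.g. \code{2000:2008}; the last grid
#'   year must not exceed \code{tau}.
#' @return A data.frame of class \code{"panel_data"} with columns
#'   \code{id}, \code{year}, \code{response}.
#' @examples
#' des <- study_design(2004, 2009)
#' dat <- validate_dataset(
#'   data.frame(d = 2001.2, y = 0, c_tilde = 4, delta = 1), des)
#' build_panel(dat, year_grid = 2002:2008)
#' @export
build_panel <- function(dataset, design = NULL, year_grid = 2000:2008) {
  if (is.null(design)) design <- design_of(dataset)
  design <- as_study_design(design)
  if (length(year_grid) < 2L) stop("year grid must contain >= 2 years")
  year_grid <- sort(as.integer(year_grid))
  if (!all(diff(year_grid) == 1L)) stop("year grid must be consecutive")
  if (max(year_grid) > design$tau)
    stop("year grid extends beyond the sampling time tau")

  grid <- expand.grid(i = seq_len(nrow(dataset)), year = year_grid)
  grid <- grid[dataset$d[grid$i] < grid$year, , drop = FALSE]
  change <- ifelse(dataset$y == 1, dataset$d,
                   ifelse(dataset$delta == 1,
                          dataset$d + dataset$c_tilde, Inf))
  out <- data.frame(id = dataset$id[grid$i],
                    year = grid$year,
                    response = as.integer(change[grid$i] <= grid$year))
  out <- out[order(out$id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, design = design, year_grid = year_grid,
            class = c("panel_data", "data.frame"))
}

#' Marginal yearly-rate model by GEE (independence working correlation)
#'
#' Fits the saturated marginal binomial model with one indicator per grid
#' year and no intercept, clustered by subject, under an independence
#' working correlation.  For this saturated design the GEE point estimates
#' have closed form: with identity link the year coefficients are exactly
#' the raw yearly proportions, and with logit link their logits.  The
#' covariance is the cluster (subject) sandwich.
#'
#' A year cell at proportion 0 or 1 makes the logit fit non-estimable:
#' the fit is flagged \code{converged = FALSE} and downstream tests
#' propagate \code{NA}.
#'
#' @param panel a \code{panel_data} object from [build_panel()].
#' @param link \code{"identity"} or \code{"logit"}.
#' @return An object of class \code{"gee_fit"}: list with
#'   \code{year_coefficients} (named by year), \code{cov_robust},
#'   \code{link}, \code{n_subjects}, \code{n_rows}, \code{converged},
#'   \code{year_grid}.
#' @export
fit_yearly_rates_gee <- function(panel, link = c("identity", "logit")) {
  link <- match.arg(link)
  if (nrow(panel) == 0L) stop("empty panel")
  year_grid <- attr(panel, "year_grid")
  if (is.null(year_grid)) year_grid <- sort(unique(panel$year))
  yrs <- as.character(year_grid)

  idx <- match(panel$year, year_grid)
  n_y <- tabulate(idx, length(year_grid))
  p_y <- vapply(seq_along(year_grid), function(j)
    if (n_y[j] > 0L) mean(panel$response[idx == j]) else NA_real_,
    numeric(1))

  # a cell at proportion 0 or 1 breaks the logit coefficients and, for
  # either link, the binomial-variance weights of the sandwich
  estimable <- n_y > 0L & !is.na(p_y) & p_y > 0 & p_y < 1
  converged <- all(estimable)
  coefs <- switch(link, identity = p_y, logit = stats::qlogis(p_y))
  names(coefs) <- yrs

  n_subjects <- length(unique(panel$id))
  cov_robust <- matrix(NA_real_, length(year_grid), length(year_grid),
                       dimnames = list(yrs, yrs))
  rank_deficient <- n_subjects < 2L
  if (converged && !rank_deficient) {
    v_y <- p_y * (1 - p_y)
    # per-row score and bread diagonal; D V^{-1} cancels for logit
    score_w <- switch(link,
      identity = (panel$response - p_y[idx]) / v_y[idx],
      logit    = (panel$response - p_y[idx]))
    a_diag <- switch(link,
      identity = n_y / v_y,
      logit    = n_y * v_y)
    sc <- matrix(0, nrow(panel), length(year_grid))
    sc[cbind(seq_len(nrow(panel)), idx)] <- score_w
    meat <- crossprod(rowsum(sc, as.character(panel$id)))
    cov_robust <- diag(1 / a_diag) %*% meat %*% diag(1 / a_diag)
    dimnames(cov_robust) <- list(yrs, yrs)
  }
  if (rank_deficient) converged <- FALSE
  structure(list(link = link, year_grid = year_grid,
                 year_coefficients = coefs,
                 proportions = stats::setNames(p_y, yrs),
                 cov_robust = cov_robust,
                 working = "independence",
                 n_subjects = n_subjects, n_rows = nrow(panel),
                 converged = converged,
                 rank_deficient = rank_deficient),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE yearly-rate fit (link =", x$link,
      ", working = independence),", x$n_subjects, "subjects,",
      x$n_rows, "rows\n")
  if (!x$converged) cat("  NOT converged / non-estimable\n")
  print(round(x$year_coefficients, 4))
  invisible(x)
}

#' Pre/post average-slope contrast test
#'
#' Tests whether the average yearly change of the status rate differs
#' after the change point: \code{slope_pre = (mu_t0 - mu_first)/(t0 -
#' first)}, \code{slope_post = (mu_last - mu_t0)/(last - t0)} on the year
#' coefficients (identity link: proportions; logit link: the linear
#' predictor), \code{diff = slope_post - slope_pre}, with variance from
#' the contrast \code{c' Sigma c} on the robust covariance and a
#' two-sided normal p-value.  Note the ceiling artifact: when the rate is
#' already high before t0 the post slope is bounded above by
#' \code{(1 - mu_t0)/(last - t0)}, so the contrast cannot detect further
#' increases.
#'
#' @param geefit a converged [fit_yearly_rates_gee()] result.
#' @param design optional [study_design()]; \code{t0} must be an interior
#'   grid year.
#' @param year_grid defaults to the fit's grid.
#' @return An object of class \code{"slope_contrast"}: list with
#'   \code{slope_pre}, \code{slope_post}, \code{diff}, \code{se_diff},
#'   \code{z}, \code{p_value}, \code{converged}.  A non-converged fit
#'   yields \code{NA} throughout (no error).
#' @export
average_slope_contrast_test <- function(geefit, design,
                                        year_grid = geefit$year_grid) {
  design <- as_study_design(design)
  t0y <- design$t0
  if (!(t0y %in% year_grid) || t0y == min(year_grid) ||
      t0y == max(year_grid))
    stop("t0 must be an interior year of the grid")
  out <- structure(list(slope_pre = NA_real_, slope_post = NA_real_,
                        diff = NA_real_, se_diff = NA_real_,
                        z = NA_real_, p_value = NA_real_,
                        converged = geefit$converged),
                   class = "slope_contrast")
  if (!geefit$converged) return(out)

  mu <- geefit$year_coefficients
  yrs <- year_grid
  first <- min(yrs); last <- max(yrs)
  cvec <- stats::setNames(numeric(length(yrs)), as.character(yrs))
  cvec[as.character(first)] <- 1 / (t0y - first)
  cvec[as.character(last)] <- 1 / (last - t0y)
  cvec[as.character(t0y)] <- -1 / (last - t0y) - 1 / (t0y - first)

  out$slope_pre <- (mu[[as.character(t0y)]] - mu[[as.character(first)]]) /
    (t0y - first)
  out$slope_post <- (mu[[as.character(last)]] - mu[[as.character(t0y)]]) /
    (last - t0y)
  out$diff <- sum(cvec * mu)
  out$se_diff <- sqrt(drop(t(cvec) %*% geefit$cov_robust %*% cvec))
  out$z <- out$diff / out$se_diff
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out
}

#' @export
print.slope_contrast <- function(x, ...) {
  if (!x$converged) {
    cat("Average-slope contrast: NA (GEE fit not converged)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Average-slope contrast: pre %.4f, post %.4f, diff %.4f (se %.4f), z = %.3f, p = %.4g\n",
    x$slope_pre, x$slope_post, x$diff, x$se_diff, x$z, x$p_value))
  invisible(x)
}
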