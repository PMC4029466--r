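#' Combined 2-df change-point test
#'
#' Adds the per-part statistics for the intervention effect — likelihood
#' ratio (default) or model-based Wald — and refers the sum to a
#' chi-squared distribution with two degrees of freedom; for df = 2 the
#' upper-tail p-value is exactly \code{exp(-statistic / 2)}.  If one part
#' is non-identifiable (e.g. no events, or no contrast in the step
#' covariate) the test falls back to the available 1-df component, with an
#' explicit \code{downgraded} flag; both parts missing is an error.
#'
#' @param binfit a [fit_binomial_part()] result.
#' @param coxfit a [fit_cox_part()] result.
#' @param method \code{"lr"} or \code{"wald"}.
#' @return An object of class \code{"combined_test"}: list with
#'   \code{method}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{components} (binomial, cox), \code{downgraded}.
#' @examples
#' dat <- simulate_survey(scenario_from_levels("Low", "High"), seed = 1)
#' combined_change_test(fit_binomial_part(dat), fit_cox_part(dat))
#' @export
combined_change_test <- function(binfit, coxfit, method = c("lr", "wald")) {
  stopifnot(inherits(binfit, "binomial_part_fit"),
            inherits(coxfit, "cox_part_fit"))
  method <- match.arg(method)

  comp_bin <- if (binfit$identifiable && binfit$converged) {
    if (method == "lr") binfit$lr_stat
    else binfit$coefficients[["x"]]^2 / binfit$cov_model["x", "x"]
  } else NA_real_
  comp_cox <- if (coxfit$identifiable && coxfit$converged) {
    if (method == "lr") coxfit$lr_stat
    else coxfit$gamma^2 / coxfit$cov_model["z", "z"]
  } else NA_real_

  finish_combined(comp_bin, comp_cox,
                  method = if (method == "lr") "LR" else "Wald")
}

#' Cluster-robust combined Wald test Q
#'
#' For clustered (multi-site) data the two parts are fitted with
#' cluster-grouped sandwich variances and the 2-df statistic is
#' \code{Q = beta1^2 / Vr(beta1) + gamma^2 / Vr(gamma)}, referred to
#' chi-squared(2).  Adding the two 1-df Wald statistics is valid because
#' the binomial-Cox cross-blocks of the stacked sandwich covariance are
#' zero (the two estimating equations share no parameters and their score
#' cross-products vanish in expectation).
#'
#' @param binfit a [fit_binomial_part()] result fitted with
#'   \code{cluster_robust = TRUE}.
#' @param coxfit a [fit_cox_part()] result fitted with
#'   \code{cluster_robust = TRUE}.
#' @return A \code{"combined_test"} with \code{method = "robust-Wald"}.
#' @export
clustered_robust_test <- function(binfit, coxfit) {
  stopifnot(inherits(binfit, "binomial_part_fit"),
            inherits(coxfit, "cox_part_fit"))
  if (binfit$identifiable && is.null(binfit$cov_robust))
    stop("binomial part has no robust covariance; refit with ",
         "cluster_robust = TRUE")
  if (coxfit$identifiable && is.null(coxfit$cov_robust))
    stop("Cox part has no robust covariance; refit with ",
         "cluster_robust = TRUE")
  comp_bin <- if (binfit$identifiable && binfit$converged)
    binfit$coefficients[["x"]]^2 / binfit$cov_robust["x", "x"]
  else NA_real_
  comp_cox <- if (coxfit$identifiable && coxfit$converged)
    coxfit$gamma^2 / coxfit$cov_robust["z", "z"]
  else NA_real_
  finish_combined(comp_bin, comp_cox, method = "robust-Wald")
}

finish_combined <- function(comp_bin, comp_cox, method) {
  if (is.na(comp_bin) && is.na(comp_cox))
    stop("both parts non-identifiable or non-converged: no test available")
  downgraded <- is.na(comp_bin) || is.na(comp_cox)
  statistic <- sum(c(comp_bin, comp_cox), na.rm = TRUE)
  df <- if (downgraded) 1L else 2L
  structure(list(method = method,
                 statistic = statistic,
                 df = df,
                 p_value = chisq_p(statistic, df),
                 components = c(binomial = comp_bin, cox = comp_cox),
                 downgraded = downgraded),
            class = "combined_test")
}

#' @export
print.combined_test <- function(x, ...) {
  cat(sprintf("Combined change-point test (%s): statistic = %.4f on %d df, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  cat(sprintf("  components: binomial %.4f, Cox %.4f%s\n",
              x$components[1], x$components[2],
              if (x$downgraded) "  [downgraded to 1 df]" else ""))
  invisible(x)
}
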