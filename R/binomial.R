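#' Binomial part of the mixture: status change at entry
#'
#' Fits the regression \code{g(pi_i) = beta0 + beta1 * x_i (+ extras)} by
#' maximum likelihood, where \code{pi_i} is the probability that subject i
#' acquires the status exactly at entry (\code{y = 1}) and
#' \code{x_i = 1\{d_i >= t0\}} is the derived pre/post indicator.  All
#' subjects contribute.  The likelihood-ratio statistic tests
#' \code{beta1 = 0} against the nested model without \code{x}.
#'
#' The logit link is the default; the log link gives coefficients
#' interpretable as log prevalence ratios but can fail to converge when
#' fitted probabilities approach 1 — such failures are flagged
#' (\code{converged = FALSE} with a diagnostic), never silently ignored.
#'
#' @param dataset a validated \code{subject_data} object.
#' @param design optional [study_design()]; defaults to the attached one.
#' @param link one of \code{"logit"}, \code{"log"}, \code{"probit"},
#'   \code{"cloglog"}.
#' @param extra_covariates character vector of extra column names to enter
#'   the linear predictor (e.g. year of career start).
#' @param cluster_robust if \code{TRUE}, also compute the cluster-grouped
#'   sandwich covariance (clusters from the \code{cluster} column).
#' @return An object of class \code{"binomial_part_fit"}: list with
#'   \code{coefficients}, \code{cov_model}, \code{cov_robust} (or NULL),
#'   \code{loglik}, \code{lr_stat}, \code{n}, \code{link},
#'   \code{converged}, \code{identifiable}, \code{message}, \code{fit}
#'   (the underlying glm).
#' @examples
#' des <- study_design(2004, 2009)
#' dat <- simulate_survey(scenario_from_levels("Low", "High"), seed = 1)
#' fit_binomial_part(dat)
#' @export
fit_binomial_part <- function(dataset, design = NULL, link = "logit",
                              extra_covariates = character(0),
                              cluster_robust = FALSE) {
  if (is.null(design)) design <- design_of(dataset)
  design <- as_study_design(design)
  link <- match.arg(link, c("logit", "log", "probit", "cloglog"))
  missing_cov <- setdiff(extra_covariates, names(dataset))
  if (length(missing_cov))
    stop("extra covariate(s) not in dataset: ",
         paste(missing_cov, collapse = ", "))

  df <- data.frame(.y = dataset$y,
                   .x = as.integer(dataset$d >= design$t0))
  for (v in extra_covariates) df[[v]] <- dataset[[v]]

  out <- list(link = link, n = nrow(df), design = design,
              cov_robust = NULL, message = NULL)
  class(out) <- "binomial_part_fit"

  if (length(unique(df$.y)) == 1L) {
    out$identifiable <- FALSE
    out$converged <- FALSE
    out$message <- "all y identical: binomial part non-identifiable"
    out$coefficients <- NULL
    out$lr_stat <- NA_real_
    return(out)
  }
  out$identifiable <- TRUE

  rhs <- paste(c(".x", extra_covariates), collapse = " + ")
  fml_full <- stats::as.formula(paste(".y ~", rhs))
  fml_null <- if (length(extra_covariates))
    stats::as.formula(paste(".y ~", paste(extra_covariates, collapse = " + ")))
  else stats::as.formula(".y ~ 1")

  fit_one <- function(fml) {
    warn <- NULL
    res <- withCallingHandlers(
      tryCatch(stats::glm(fml, family = stats::binomial(link = link),
                          data = df),
               error = function(e) e),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = res, warn = warn)
  }
  full <- fit_one(fml_full)
  if (inherits(full$fit, "error")) {
    out$converged <- FALSE
    out$message <- paste0("glm failed (link = ", link, "): ",
                          conditionMessage(full$fit))
    out$coefficients <- NULL
    out$lr_stat <- NA_real_
    return(out)
  }
  fit <- full$fit
  out$fit <- fit
  cf <- stats::coef(fit)
  names(cf)[names(cf) == ".x"] <- "x"
  names(cf)[names(cf) == "(Intercept)"] <- "intercept"
  out$coefficients <- cf
  out$cov_model <- stats::vcov(fit)
  dimnames(out$cov_model) <- list(names(cf), names(cf))
  out$loglik <- as.numeric(stats::logLik(fit))
  out$converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    all(is.finite(cf))
  if (!is.null(full$warn))
    out$message <- paste(unique(full$warn), collapse = "; ")

  null <- fit_one(fml_null)
  out$lr_stat <- if (inherits(null$fit, "error") ||
                     !isTRUE(null$fit$converged)) NA_real_
  else max(0, 2 * (out$loglik - as.numeric(stats::logLik(null$fit))))

  if (cluster_robust) {
    cl <- dataset$cluster
    if (all(is.na(cl)))
      stop("cluster_robust = TRUE but the 'cluster' column is all NA")
    out$cov_robust <- glm_cluster_vcov(fit, cl)
    dimnames(out$cov_robust) <- list(names(cf), names(cf))
    out$n_clusters <- length(unique(cl))
  }
  out
}

#' @export
print.binomial_part_fit <- function(x, ...) {
  cat("Binomial part (link =", x$link, "), n =", x$n, "\n")
  if (!x$identifiable) {
    cat("  non-identifiable:", x$message, "\n")
    return(invisible(x))
  }
  if (!x$converged) cat("  NOT converged:", x$message, "\n")
  cf <- x$coefficients
  se <- sqrt(diag(x$cov_model))
  for (i in seq_along(cf))
    cat(sprintf("  %-12s %9.4f (se %.4f)\n", names(cf)[i], cf[i], se[i]))
  if (!is.null(x$cov_robust))
    cat(sprintf("  robust se(x) %.4f  (%d clusters)\n",
                sqrt(x$cov_robust["x", "x"]), x$n_clusters))
  cat(sprintf("  LR stat (x = 0): %.4f\n", x$lr_stat))
  invisible(x)
}
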