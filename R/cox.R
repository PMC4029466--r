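#' Cox part of the mixture: acquisition during the career
#'
#' Fits \code{h(t) = h0(t) exp(gamma z(t))} by partial likelihood on the
#' subjects with a positive duration (\code{y = 0}), where t is time since
#' career start and \code{z(t) = 1\{d + t >= t0\}} is the time-dependent
#' step covariate, represented in counting-process form by
#' [split_episodes()].  The likelihood-ratio statistic tests
#' \code{gamma = 0}.
#'
#' @param dataset a validated \code{subject_data} object (subjects with
#'   \code{y = 1} are excluded internally).
#' @param design optional [study_design()]; defaults to the attached one.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param extra_covariates character vector of time-fixed covariate columns
#'   to include.
#' @param calendar_year if \code{TRUE}, episodes are additionally split at
#'   integer calendar-year boundaries and the interval-constant covariate
#'   \code{year_c} (calendar year at interval start, centered at
#'   \code{floor(t0)}) enters the model — the "calendar year as
#'   time-varying covariate" variant.
#' @param cluster_robust if \code{TRUE}, the marginal-approach sandwich
#'   covariance grouped by the \code{cluster} column is computed.
#' @param baseline if \code{TRUE}, include the Breslow cumulative baseline
#'   hazard estimate.
#' @return An object of class \code{"cox_part_fit"}: list with
#'   \code{gamma}, \code{coefficients}, \code{cov_model},
#'   \code{cov_robust} (or NULL), \code{pll}, \code{lr_stat}, \code{ties},
#'   \code{n} (subjects), \code{n_events}, \code{identifiable},
#'   \code{converged}, \code{baseline} (or NULL), \code{fit} (the
#'   underlying coxph).
#' @examples
#' dat <- simulate_survey(scenario_from_levels("Low", "High"), seed = 1)
#' fit_cox_part(dat)
#' @export
fit_cox_part <- function(dataset, design = NULL, ties = "efron",
                         extra_covariates = character(0),
                         calendar_year = FALSE,
                         cluster_robust = FALSE, baseline = FALSE) {
  if (is.null(design)) design <- design_of(dataset)
  design <- as_study_design(design)
  ties <- match.arg(ties, c("efron", "breslow"))

  dat0 <- dataset[dataset$y == 0, , drop = FALSE]
  out <- list(ties = ties, design = design, cov_robust = NULL,
              baseline = NULL, approximation = NULL,
              n = nrow(dat0), message = NULL)
  class(out) <- "cox_part_fit"
  if (nrow(dat0) == 0L) {
    out$identifiable <- FALSE
    out$converged <- FALSE
    out$n_events <- 0L
    out$message <- "no y = 0 subjects: Cox part empty (binomial-only analysis)"
    out$gamma <- NA_real_
    out$lr_stat <- NA_real_
    return(out)
  }
  ep <- split_episodes(dataset, design)
  if (calendar_year) ep <- split_calendar_years(ep, dataset, design)
  fit_cox_episodes(ep, out, extra_covariates, cluster_robust, baseline)
}

# shared fitting backend for fit_cox_part / fit_single_cox_approx
fit_cox_episodes <- function(ep, out, extra_covariates, cluster_robust,
                             baseline) {
  missing_cov <- setdiff(extra_covariates, names(ep))
  if (length(missing_cov))
    stop("extra covariate(s) not in episodes: ",
         paste(missing_cov, collapse = ", "))
  out$n_events <- sum(ep$event)
  out$episodes <- ep

  # no event, or no contrast in z at any event's risk set -> flag
  if (out$n_events == 0L || length(unique(ep$z)) == 1L) {
    out$identifiable <- FALSE
    out$converged <- FALSE
    out$message <- if (out$n_events == 0L) "no events in the Cox part"
    else "z constant across all episodes: gamma non-identifiable"
    out$gamma <- NA_real_
    out$lr_stat <- NA_real_
    return(out)
  }
  out$identifiable <- TRUE

  rhs <- paste(c("z", extra_covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(start, stop, event) ~", rhs))
  cl <- if (cluster_robust) {
    if (all(is.na(ep$cluster)))
      stop("cluster_robust = TRUE but the 'cluster' column is all NA")
    as.character(ep$cluster)
  } else NULL

  fit <- tryCatch(
    survival::coxph(fml, data = ep, ties = out$ties, cluster = cl,
                    x = FALSE),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$converged <- FALSE
    out$gamma <- NA_real_
    out$lr_stat <- NA_real_
    out$message <- paste("coxph failed:", conditionMessage(fit))
    return(out)
  }
  out$fit <- fit
  cf <- stats::coef(fit)
  out$coefficients <- cf
  out$gamma <- unname(cf["z"])
  if (cluster_robust) {
    out$cov_robust <- fit$var
    dimnames(out$cov_robust) <- list(names(cf), names(cf))
    out$cov_model <- fit$naive.var
    out$n_clusters <- length(unique(cl))
  } else {
    out$cov_model <- fit$var
  }
  dimnames(out$cov_model) <- list(names(cf), names(cf))
  out$pll <- fit$loglik[2]
  out$converged <- all(is.finite(cf)) &&
    all(is.finite(diag(out$cov_model)))

  out$lr_stat <- if (length(extra_covariates) == 0L) {
    max(0, 2 * (fit$loglik[2] - fit$loglik[1]))
  } else {
    fml0 <- stats::as.formula(
      paste("survival::Surv(start, stop, event) ~",
            paste(extra_covariates, collapse = " + ")))
    fit0 <- survival::coxph(fml0, data = ep, ties = out$ties)
    max(0, 2 * (fit$loglik[2] - fit0$loglik[2]))
  }
  if (baseline)
    out$baseline <- survival::basehaz(fit, centered = FALSE)
  out
}

# split episode rows at integer calendar-year boundaries; adds the
# interval-constant covariate year_c = floor(calendar year at interval
# start) - floor(t0)
split_calendar_years <- function(ep, dataset, design) {
  d_by_id <- stats::setNames(dataset$d, dataset$id)
  rows <- lapply(seq_len(nrow(ep)), function(i) {
    r <- ep[i, , drop = FALSE]
    d <- d_by_id[[as.character(r$id)]]
    # career-time cut points at calendar new years strictly inside (start, stop)
    yrs <- seq(ceiling(d + r$start), floor(d + r$stop))
    cuts <- setdiff(yrs - d, c(r$start, r$stop))
    cuts <- cuts[cuts > r$start & cuts < r$stop]
    bounds <- c(r$start, sort(cuts), r$stop)
    k <- length(bounds) - 1L
    sub <- r[rep(1L, k), , drop = FALSE]
    sub$start <- bounds[-(k + 1L)]
    sub$stop <- bounds[-1L]
    sub$event <- c(rep(0L, k - 1L), r$event)
    sub$year_c <- floor(d + sub$start) - floor(design$t0)
    sub
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, design = design, class = c("episode_data", "data.frame"))
}

#' Single-Cox approximation of the mixture
#'
#' All subjects enter one Cox fit; those with the status change at entry
#' (\code{y = 1}) are given a very small positive event time
#' \code{epsilon} (default 1 day = 1/365.25 years).  Convenient, but not
#' recommended when entry acquirers are a non-negligible fraction of the
#' sample; the result carries \code{approximation = "single-cox"}.
#'
#' @inheritParams fit_cox_part
#' @param epsilon imputed event time for entry acquirers, years; must be
#'   positive.  A warning is issued when \code{epsilon} is not smaller
#'   than the smallest genuine positive duration (event ordering would be
#'   distorted).
#' @return A \code{"cox_part_fit"} as from [fit_cox_part()].
#' @export
fit_single_cox_approx <- function(dataset, design = NULL,
                                  epsilon = 1 / 365.25, ties = "efron",
                                  extra_covariates = character(0),
                                  cluster_robust = FALSE,
                                  baseline = FALSE) {
  if (is.null(design)) design <- design_of(dataset)
  design <- as_study_design(design)
  stopifnot(epsilon > 0)
  ties <- match.arg(ties, c("efron", "breslow"))

  pos <- dataset$c_tilde[dataset$y == 0]
  if (length(pos) && epsilon >= min(pos))
    warning("epsilon (", epsilon, ") is not below the smallest positive ",
            "duration (", min(pos), "): event ordering is distorted")

  mod <- as.data.frame(dataset)
  at0 <- mod$y == 1
  mod$c_tilde[at0] <- epsilon
  mod$delta[at0] <- 1L
  mod$y <- 0L
  mod <- validate_dataset(mod, design)

  out <- list(ties = ties, design = design, cov_robust = NULL,
              baseline = NULL, n = nrow(mod), message = NULL,
              approximation = "single-cox", epsilon = epsilon)
  class(out) <- "cox_part_fit"
  ep <- split_episodes(mod, design)
  fit_cox_episodes(ep, out, extra_covariates, cluster_robust, baseline)
}

#' @export
print.cox_part_fit <- function(x, ...) {
  cat("Cox part (ties =", x$ties,
      if (!is.null(x$approximation)) paste0(", ", x$approximation),
      "), n =", x$n, ", events =", x$n_events, "\n")
  if (!x$identifiable) {
    cat("  non-identifiable:", x$message, "\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  se <- sqrt(diag(x$cov_model))
  for (i in seq_along(cf))
    cat(sprintf("  %-12s %9.4f (se %.4f)\n", names(cf)[i], cf[i], se[i]))
  if (!is.null(x$cov_robust))
    cat(sprintf("  robust se(z) %.4f  (%d clusters)\n",
                sqrt(x$cov_robust["z", "z"]), x$n_clusters))
  cat(sprintf("  LR stat (gamma = 0): %.4f\n", x$lr_stat))
  invisible(x)
}
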