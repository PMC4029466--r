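#' Study design: sampling time and hypothesized change point
#'
#' A cross-sectional survey recruits members of the target population at
#' calendar time \code{tau}; interest is in whether the acquisition of a
#' permanent status changed at an earlier, known calendar time \code{t0}
#' (e.g. the start of an intervention).  All calendar times are decimal
#' years on a single continuous axis; time since population entry for a
#' subject with entry time \code{d} is \code{calendar time - d}.
#'
#' @param t0 calendar time of the hypothesized change (decimal years).
#' @param tau calendar time of data collection (decimal years); must
#'   exceed \code{t0}.
#' @return An object of class \code{"study_design"}: a list with elements
#'   \code{t0} and \code{tau}.
#' @examples
#' study_design(t0 = 2004, tau = 2009)
#' @export
study_design <- function(t0, tau) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (t0 >= tau)
    stop("'t0' must be strictly before the sampling time 'tau' (t0 < tau)")
  structure(list(t0 = as.numeric(t0), tau = as.numeric(tau)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design: change point t0 =", x$t0, ", sampling time tau =",
      x$tau, "\n")
  invisible(x)
}

as_study_design <- function(design) {
  if (!inherits(design, "study_design"))
    stop("'design' must be a study_design object; see study_design()")
  design
}
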