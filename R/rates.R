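#' Crude status-rate curve R_t = U_t / N_t
#'
#' At each calendar time \code{t}, \code{n_t} counts subjects whose career
#' began strictly before \code{t} and \code{u_t} counts those among them
#' whose status change happened strictly before \code{t} (entry acquirers
#' change status at entry; others at calendar time \code{d + c_tilde} when
#' \code{delta = 1}).  \code{r_t = u_t / n_t} is the crude proportion with
#' the status at time \code{t}; it is \code{NA} (flagged, no error) where
#' \code{n_t = 0}.
#'
#' @param dataset a validated \code{subject_data} object.
#' @param times numeric vector of calendar times.
#' @return A data.frame of class \code{"rate_curve"} with columns
#'   \code{time}, \code{n_t}, \code{u_t}, \code{r_t}.
#' @examples
#' des <- study_design(2004, 2009)
#' df <- data.frame(d = c(2000, 2001, 2002), y = c(1, 0, 0),
#'                  c_tilde = c(0, 2, 7), delta = c(1, 1, 0))
#' crude_rate_curve(validate_dataset(df, des), 2000:2009)
#' @export
crude_rate_curve <- function(dataset, times) {
  stopifnot(is.numeric(times), length(times) > 0L)
  d <- dataset$d
  # calendar time of the status change; +Inf when censored
  change <- ifelse(dataset$y == 1, d,
                   ifelse(dataset$delta == 1, d + dataset$c_tilde, Inf))
  n_t <- vapply(times, function(t) sum(d < t), integer(1))
  u_t <- vapply(times, function(t) sum(d < t & change < t), integer(1))
  r_t <- ifelse(n_t > 0L, u_t / n_t, NA_real_)
  structure(data.frame(time = times, n_t = n_t, u_t = u_t, r_t = r_t),
            class = c("rate_curve", "data.frame"))
}
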