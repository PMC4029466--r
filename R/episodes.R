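#' Expand positive-duration subjects into counting-process episodes
#'
#' For the Cox fit with the time-dependent step covariate
#' \code{z(t) = 1\{calendar time >= t0\}}, each subject with a positive
#' duration (\code{y = 0}) is represented on the career-time axis as one or
#' two \code{(start, stop]} intervals over which \code{z} is constant.
#' With \code{s* = t0 - d}:
#' \itemize{
#'   \item \code{d >= t0}: single row \code{(0, c_tilde]} with \code{z = 1};
#'   \item \code{0 < s* < c_tilde}: rows \code{(0, s*]} with \code{z = 0},
#'     event 0, and \code{(s*, c_tilde]} with \code{z = 1}, event
#'     \code{delta};
#'   \item \code{c_tilde <= s*}: single row \code{(0, c_tilde]} with
#'     \code{z = 0}, except that an event falling exactly at calendar time
#'     \code{t0} carries \code{z = 1} (the covariate is 1 when
#'     \code{t >= t0}).
#' }
#' Subjects with \code{y = 1} contribute nothing to the Cox part and are
#' dropped (or rejected, see \code{drop_entry_acquirers}).
#'
#' @param dataset a validated \code{subject_data} object.
#' @param design optional [study_design()]; defaults to the one attached to
#'   \code{dataset}.
#' @param drop_entry_acquirers if \code{TRUE} (default) subjects with
#'   \code{y = 1} are silently excluded; if \code{FALSE} their presence is
#'   an error.
#' @return A data.frame of class \code{"episode_data"} with columns
#'   \code{id}, \code{start}, \code{stop}, \code{event}, \code{z}, then
#'   \code{cluster} and any extra covariates (interval-constant).
#' @examples
#' des <- study_design(2004, 2009)
#' df <- data.frame(d = 2000, y = 0, c_tilde = 7, delta = 1)
#' split_episodes(validate_dataset(df, des))
#' @export
split_episodes <- function(dataset, design = NULL,
                           drop_entry_acquirers = TRUE) {
  if (is.null(design)) design <- design_of(dataset)
  design <- as_study_design(design)
  if (any(dataset$y == 1)) {
    if (!drop_entry_acquirers)
      stop("subjects with y = 1 (status change at entry) cannot enter ",
           "the Cox part; remove them or use drop_entry_acquirers = TRUE")
    dataset <- dataset[dataset$y == 0, , drop = FALSE]
  }
  if (nrow(dataset) == 0L)
    stop("no subjects with y = 0: the Cox part is empty")
  if (any(dataset$c_tilde <= 0))
    stop("y = 0 subjects must have c_tilde > 0")

  extras <- c("cluster", covariate_names(dataset))
  sstar <- design$t0 - dataset$d
  ct <- dataset$c_tilde
  del <- as.integer(dataset$delta)

  post <- which(sstar <= 0)              # entered at or after t0
  span <- which(sstar > 0 & sstar < ct)  # change point inside follow-up
  pre  <- which(sstar >= ct)             # follow-up ends at or before t0

  idx   <- c(post, span, span, pre)
  start <- c(rep(0, length(post)), rep(0, length(span)), sstar[span],
             rep(0, length(pre)))
  stop_ <- c(ct[post], sstar[span], ct[span], ct[pre])
  event <- c(del[post], rep(0L, length(span)), del[span], del[pre])
  # an event exactly at calendar t0 carries z = 1 (z(t) = 1 when t >= t0)
  z <- c(rep(1L, length(post)), rep(0L, length(span)),
         rep(1L, length(span)),
         as.integer(ct[pre] == sstar[pre] & del[pre] == 1L))
  ord <- order(idx, start)
  out <- cbind(data.frame(id = dataset$id[idx[ord]], start = start[ord],
                          stop = stop_[ord], event = event[ord],
                          z = z[ord]),
               as.data.frame(dataset)[idx[ord], extras, drop = FALSE],
               row.names = NULL)
  structure(out, design = design, class = c("episode_data", "data.frame"))
}

#' Write episodes as a counting-process CSV
#'
#' Columns \code{id,start,stop,event,z[,...]}, directly consumable by
#' start-stop survival fitters.
#'
#' @param episodes an \code{episode_data} object from [split_episodes()].
#' @param file output path.
#' @export
write_episode_csv <- function(episodes, file) {
  utils::write.csv(as.data.frame(episodes), file, row.names = FALSE,
                   na = "")
  invisible(file)
}
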