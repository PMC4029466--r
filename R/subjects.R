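#' Subject-level data for the Cox-binomial change-point analysis
#'
#' Each row describes one sampled individual's reconstructed history:
#' \describe{
#'   \item{\code{id}}{opaque subject label (unique).}
#'   \item{\code{cluster}}{optional cluster label (e.g. district); may be
#'     \code{NA} throughout.}
#'   \item{\code{d}}{calendar time of population entry (career start),
#'     decimal years.}
#'   \item{\code{y}}{0/1 status-at-entry indicator; 1 means the permanent
#'     status was acquired exactly at entry (duration 0).}
#'   \item{\code{c_tilde}}{observed duration in the population before the
#'     status change or censoring, years: \code{min(C, tau - d)}.}
#'   \item{\code{delta}}{0/1 event indicator; 1 if the status change was
#'     observed before the survey at \code{tau}, 0 if right-censored
#'     (in which case \code{c_tilde = tau - d}).}
#' }
#' Any further columns are carried along as covariates.  The pre/post
#' indicator \code{x = 1\{d >= t0\}} is derived, never stored; an entry
#' exactly at \code{t0} counts as post (right-continuity convention).
#'
#' @param records a data.frame with at least columns \code{d}, \code{y},
#'   \code{c_tilde}, \code{delta}; \code{id} and \code{cluster} are added
#'   if absent.
#' @param design a [study_design()].
#' @return A validated data.frame of class \code{"subject_data"} with the
#'   design attached as attribute \code{"design"}.
#' @details Validation enforces the cross-sectional observation scheme:
#'   \code{d < tau} (entry before sampling), \code{0 <= c_tilde <= tau - d},
#'   \code{y = 1} exactly when \code{c_tilde = 0} and \code{delta = 1}, and
#'   censoring only at the survey (\code{delta = 0} implies
#'   \code{c_tilde = tau - d}).  All violations are reported together with
#'   the offending record ids.
#' @examples
#' des <- study_design(2004, 2009)
#' df <- data.frame(d = c(2000, 2006), y = c(1, 0),
#'                  c_tilde = c(0, 3), delta = c(1, 0))
#' validate_dataset(df, des)
#' @export
validate_dataset <- function(records, design) {
  design <- as_study_design(design)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("'records' must be non-empty")
  need <- c("d", "y", "c_tilde", "delta")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(records$id)) records$id <- seq_len(nrow(records))
  if (anyDuplicated(records$id)) stop("subject 'id' values must be unique")
  if (is.null(records$cluster)) records$cluster <- NA_character_
  for (v in need)
    if (!is.numeric(records[[v]]))
      stop("column '", v, "' must be numeric")
  if (!all(records$y %in% c(0, 1)) || !all(records$delta %in% c(0, 1)))
    stop("'y' and 'delta' must be 0/1")

  tol <- 1e-8
  tau <- design$tau
  bad <- list(
    "d >= tau (entry not before sampling)" = records$d >= tau,
    "c_tilde < 0" = records$c_tilde < -tol,
    "c_tilde > tau - d" = records$c_tilde > tau - records$d + tol,
    "y=1 but (c_tilde, delta) != (0, 1)" =
      records$y == 1 & !(abs(records$c_tilde) <= tol & records$delta == 1),
    "y=0 but c_tilde = 0 with delta = 1" =
      records$y == 0 & abs(records$c_tilde) <= tol & records$delta == 1,
    "delta=0 but c_tilde != tau-d (censoring only at tau)" =
      records$delta == 0 & abs(records$c_tilde - (tau - records$d)) > tol
  )
  msgs <- character(0)
  for (rule in names(bad)) {
    hit <- which(bad[[rule]])
    if (length(hit))
      msgs <- c(msgs, paste0("rule \"", rule, "\": record id(s) ",
                             paste(utils::head(records$id[hit], 10L),
                                   collapse = ", "),
                             if (length(hit) > 10L) " ..."))
  }
  if (length(msgs))
    stop("invalid subject data:\n  ", paste(msgs, collapse = "\n  "))

  first <- c("id", "cluster", "d", "y", "c_tilde", "delta")
  records <- records[, c(first, setdiff(names(records), first)), drop = FALSE]
  structure(records, design = design,
            class = c("subject_data", "data.frame"))
}

#' @rdname validate_dataset
#' @export
as_subject_data <- validate_dataset

design_of <- function(dataset) {
  des <- attr(dataset, "design")
  if (is.null(des))
    stop("dataset carries no study design; run validate_dataset() first")
  des
}

covariate_names <- function(dataset) {
  setdiff(names(dataset), c("id", "cluster", "d", "y", "c_tilde", "delta"))
}

#' Read / write subject-level CSV
#'
#' The canonical plain-text exchange format: header row
#' \code{id,cluster,d,y,c_tilde,delta[,<covariate>...]}, decimal years with
#' a '.' separator, empty \code{cluster} cells permitted.
#'
#' @param file path to a CSV file.
#' @param design a [study_design()]; the data are validated on read.
#' @return \code{read_subject_csv}: a validated \code{subject_data} object.
#' @export
read_subject_csv <- function(file, design) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!is.null(df$cluster)) df$cluster <- as.character(df$cluster)
  validate_dataset(df, design)
}

#' @rdname read_subject_csv
#' @param dataset a \code{subject_data} object.
#' @export
write_subject_csv <- function(dataset, file) {
  utils::write.csv(as.data.frame(dataset), file, row.names = FALSE,
                   na = "")
  invisible(file)
}
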