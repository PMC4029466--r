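#' Monte-Carlo type-I error / power study
#'
#' Reruns the full pipeline per replicate — simulate a fresh population,
#' apply the cross-sectional sampling, run each requested test — and
#' reports the proportion of replicates rejecting the null of no change at
#' t0 at level \code{alpha}.  Non-converged fits are recorded as
#' \code{NA} and excluded from that method's denominator (reported via
#' \code{na_count}), never counted as rejections.  Replicates use
#' seeds drawn deterministically from \code{seed}, so results are
#' reproducible and independent of any parallel execution order.
#'
#' @param scenarios a list of [simulation_scenario()] objects (optionally
#'   named), or a data.frame with character columns \code{pre},
#'   \code{post} of [ccu_level()] names.
#' @param reps replicates per scenario.
#' @param alpha significance level (default 0.05, two-sided).
#' @param methods subset of \code{"cox_binomial"}, \code{"gee_linear"},
#'   \code{"gee_logit"}.
#' @param seed master RNG seed.
#' @param combine statistic for the Cox-binomial combination, \code{"lr"}
#'   (default) or \code{"wald"}.
#' @param year_grid yearly panel grid for the GEE methods.
#' @param thin_to optional calibration knob: per replicate, randomly thin
#'   the included subjects to this target size before analysis.
#' @param gee_reps optionally run the GEE methods on only the first
#'   \code{gee_reps} replicates (they share the Cox-binomial replicates'
#'   samples); default all.
#' @return An object of class \code{"power_study"}: a list with
#'   \code{table} (one row per scenario x method: rejection proportion,
#'   counts, Monte-Carlo standard error), \code{sample_sizes} (realized
#'   included n and y=0 n per scenario), \code{p_values} (per-scenario
#'   replicate-by-method matrix of p-values), \code{reps}, \code{alpha},
#'   \code{seed}.
#' @examples
#' \donttest{
#' ps <- run_power_study(data.frame(pre = "Low", post = "High"),
#'                       reps = 20, seed = 1)
#' summarize_power_table(ps)
#' }
#' @export
run_power_study <- function(scenarios, reps = 1000L, alpha = 0.05,
                            methods = c("gee_linear", "gee_logit",
                                        "cox_binomial"),
                            seed = 1L, combine = "lr",
                            year_grid = 2000:2008, thin_to = NULL,
                            gee_reps = reps) {
  stopifnot(reps >= 1L, alpha > 0, alpha <= 1)
  reps <- as.integer(reps)
  gee_reps <- as.integer(gee_reps)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("gee_linear", "gee_logit",
                                   "cox_binomial"))
  if (is.data.frame(scenarios)) {
    labs <- paste(scenarios$pre, scenarios$post, sep = "/")
    scenarios <- Map(function(a, b) scenario_from_levels(a, b),
                     scenarios$pre, scenarios$post)
    names(scenarios) <- labs
  }
  if (inherits(scenarios, "simulation_scenario"))
    scenarios <- list(scenarios)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))

  rows <- list()
  sizes <- list()
  pstore <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    lab <- names(scenarios)[s]
    seeds <- replicate_seeds(seed + s - 1L, reps)
    pvals <- matrix(NA_real_, reps, length(methods),
                    dimnames = list(NULL, methods))
    n_incl <- integer(reps); n_pos <- integer(reps)
    for (r in seq_len(reps)) {
      dat <- simulate_survey(sc, seed = seeds[r], thin_to = thin_to)
      n_incl[r] <- nrow(dat)
      n_pos[r] <- sum(dat$y == 0)
      if (nrow(dat) == 0L) next
      for (m in methods) {
        if (m != "cox_binomial" && r > gee_reps) next
        pvals[r, m] <- switch(m,
          cox_binomial = p_cox_binomial(dat, combine),
          gee_linear = p_gee_slope(dat, "identity", year_grid),
          gee_logit = p_gee_slope(dat, "logit", year_grid))
      }
    }
    for (m in methods) {
      used <- if (m == "cox_binomial") reps else min(reps, gee_reps)
      p <- pvals[seq_len(used), m]
      n_ok <- sum(!is.na(p))
      rej <- if (n_ok > 0) mean(p[!is.na(p)] < alpha) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = lab, method = m, reps = used, n_used = n_ok,
        na_count = used - n_ok, rejection = rej,
        mc_se = if (n_ok > 0) sqrt(rej * (1 - rej) / n_ok) else NA_real_)
    }
    pstore[[lab]] <- pvals
    sizes[[lab]] <- data.frame(
      scenario = lab,
      n_included_min = min(n_incl), n_included_med = stats::median(n_incl),
      n_included_max = max(n_incl),
      n_pos_min = min(n_pos), n_pos_med = stats::median(n_pos),
      n_pos_max = max(n_pos))
  }
  structure(list(table = do.call(rbind, rows),
                 sample_sizes = do.call(rbind, sizes),
                 p_values = pstore,
                 reps = reps, alpha = alpha, seed = seed,
                 combine = combine),
            class = "power_study")
}

# one replicate of each method; returns the p-value or NA
p_cox_binomial <- function(dat, combine = "lr") {
  bin <- tryCatch(fit_binomial_part(dat), error = function(e) NULL)
  cox <- tryCatch(fit_cox_part(dat), error = function(e) NULL)
  if (is.null(bin) || is.null(cox)) return(NA_real_)
  tst <- tryCatch(combined_change_test(bin, cox, method = combine),
                  error = function(e) NULL)
  if (is.null(tst)) NA_real_ else tst$p_value
}

p_gee_slope <- function(dat, link, year_grid) {
  res <- tryCatch({
    panel <- build_panel(dat, year_grid = year_grid)
    gf <- fit_yearly_rates_gee(panel, link = link)
    average_slope_contrast_test(gf, design_of(dat), year_grid)
  }, error = function(e) NULL)
  if (is.null(res)) return(NA_real_)
  res$p_value
}

#' @export
print.power_study <- function(x, ...) {
  cat("Power study:", x$reps, "replicates, alpha =", x$alpha,
      ", seed =", x$seed, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Format a power study as a rejection-proportion table
#'
#' One row per scenario, one column per method; cells show the rejection
#' proportion with the Monte-Carlo standard error in parentheses, or
#' \code{"NA"} when a method produced no usable replicates.
#'
#' @param results a \code{power_study} object (or a list of them, merged).
#' @param digits rounding for the proportions.
#' @return A character-matrix data.frame; also printable as TSV with
#'   \code{write.table}.
#' @export
summarize_power_table <- function(results, digits = 3) {
  if (inherits(results, "power_study")) results <- list(results)
  tab <- do.call(rbind, lapply(results, `[[`, "table"))
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(scenario = character(0)))
  methods <- unique(tab$method)
  scen <- unique(tab$scenario)
  out <- data.frame(scenario = scen, stringsAsFactors = FALSE)
  for (m in methods) {
    cells <- vapply(scen, function(s) {
      row <- tab[tab$scenario == s & tab$method == m, ]
      if (nrow(row) == 0L || is.na(row$rejection[1])) return("NA")
      sprintf("%.*f (%.*f)", digits, row$rejection[1],
              digits, row$mc_se[1])
    }, character(1))
    out[[m]] <- cells
  }
  out
}
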