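#' Simulation scenario for the prevalent-cohort generator
#'
#' Describes the generative model of the simulation study: a population of
#' \code{n_pop} women with normally distributed birth years and career-start
#' ages, Weibull career lengths, a Bernoulli point mass at entry whose
#' probability jumps from \code{pi1} to \code{pi2} at the change point, and
#' a piecewise-exponential time to status change whose hazard jumps from
#' \code{h1} to \code{h2} at the change point.  Defaults are the study's
#' stated conditions: 800 women, birth ~ N(1973, 7^2), entry age ~
#' N(22, 4^2), career length ~ Weibull(shape 3, scale 40) with survival
#' exp(-(t/scale)^shape), t0 = 2004, tau = 2009.
#'
#' @param pi1,pi2 probability of status change at entry for careers started
#'   before / at-or-after \code{t0} (both in [0, 1]).
#' @param h1,h2 hazard of status change (per year) before / from \code{t0}
#'   on the calendar axis; both positive.
#' @param n_pop population size.
#' @param birth_mean,birth_sd mean and sd of birth calendar year.
#' @param start_age_mean,start_age_sd mean and sd of age at career start.
#' @param weib_shape,weib_scale Weibull parameters of career length (years).
#' @param design a [study_design()].
#' @return A list of class \code{"simulation_scenario"}.
#' @examples
#' simulation_scenario(pi1 = 0.2, pi2 = 0.8, h1 = 0.05, h2 = 0.25)
#' @export
simulation_scenario <- function(pi1, pi2, h1, h2,
                                n_pop = 800L,
                                birth_mean = 1973, birth_sd = 7,
                                start_age_mean = 22, start_age_sd = 4,
                                weib_shape = 3, weib_scale = 40,
                                design = study_design(2004, 2009)) {
  design <- as_study_design(design)
  stopifnot(n_pop >= 1, pi1 >= 0, pi1 <= 1, pi2 >= 0, pi2 <= 1,
            h1 > 0, h2 > 0, weib_shape > 0, weib_scale > 0,
            birth_sd > 0, start_age_sd > 0)
  structure(list(n_pop = as.integer(n_pop),
                 birth_mean = birth_mean, birth_sd = birth_sd,
                 start_age_mean = start_age_mean,
                 start_age_sd = start_age_sd,
                 weib_shape = weib_shape, weib_scale = weib_scale,
                 pi1 = pi1, pi2 = pi2, h1 = h1, h2 = h2,
                 design = design),
            class = "simulation_scenario")
}

#' Condom-use parameter levels of the simulation study
#'
#' The three named levels pair the probability of status change at entry
#' with the hazard of acquisition during the career: Low (0.2, 0.05),
#' Medium (0.5, 0.10), High (0.8, 0.25).
#'
#' @param level one of \code{"Low"}, \code{"Medium"}, \code{"High"}.
#' @return Named numeric vector \code{c(pi = ..., h = ...)}.
#' @export
ccu_level <- function(level) {
  map <- list(Low    = c(pi = 0.2, h = 0.05),
              Medium = c(pi = 0.5, h = 0.10),
              High   = c(pi = 0.8, h = 0.25))
  lv <- match.arg(level, names(map))
  map[[lv]]
}

#' Scenario from a pre/post level pair
#'
#' @param pre,post levels (see [ccu_level()]) before and after the change
#'   point.
#' @param ... passed to [simulation_scenario()].
#' @export
scenario_from_levels <- function(pre, post, ...) {
  a <- ccu_level(pre); b <- ccu_level(post)
  simulation_scenario(pi1 = a[["pi"]], pi2 = b[["pi"]],
                      h1 = a[["h"]], h2 = b[["h"]], ...)
}

#' Draw a piecewise-exponential time to status change
#'
#' Inversion sampling of the positive duration C for a subject entering at
#' calendar time \code{d}: the hazard on the career-time axis is \code{h1}
#' while calendar time is below \code{t0} and \code{h2} from \code{t0} on.
#' With \code{s* = max(t0 - d, 0)} and E ~ Exponential(1): return
#' \code{E/h1} if \code{E <= h1 s*}, else \code{s* + (E - h1 s*)/h2}.
#'
#' @param d career-start calendar time(s); vectorized.
#' @param scenario a [simulation_scenario()].
#' @return Positive durations, one per element of \code{d}.
#' @export
draw_piecewise_exponential_ccu <- function(d, scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  h1 <- scenario$h1; h2 <- scenario$h2
  sstar <- pmax(scenario$design$t0 - d, 0)
  e <- stats::rexp(length(d))
  ifelse(e <= h1 * sstar, e / h1, sstar + (e - h1 * sstar) / h2)
}

#' Simulate the latent population
#'
#' Draws \code{n_pop} individuals with birth year, career start \code{d}
#' (birth + entry age), career length \code{F}, entry-acquisition indicator
#' \code{Y ~ Bernoulli(pi1 if d < t0 else pi2)}, and duration \code{C}
#' (0 when \code{Y = 1}, else piecewise exponential).  Values are kept at
#' full floating precision; no truncation of tails.
#'
#' @param scenario a [simulation_scenario()].
#' @return A data.frame with columns \code{birth, d, f, y, c}.
#' @export
simulate_population <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n <- scenario$n_pop
  birth <- stats::rnorm(n, scenario$birth_mean, scenario$birth_sd)
  d <- birth + stats::rnorm(n, scenario$start_age_mean,
                            scenario$start_age_sd)
  f <- stats::rweibull(n, shape = scenario$weib_shape,
                       scale = scenario$weib_scale)
  pi_i <- ifelse(d < scenario$design$t0, scenario$pi1, scenario$pi2)
  y <- stats::rbinom(n, 1L, pi_i)
  cc <- numeric(n)
  pos <- y == 0L
  cc[pos] <- draw_piecewise_exponential_ccu(d[pos], scenario)
  data.frame(birth = birth, d = d, f = f, y = y, c = cc)
}

#' Apply the cross-sectional inclusion rule and censoring at tau
#'
#' Keeps individuals in the population at the survey time:
#' \code{d < tau < d + F}.  For each, the observed duration is
#' \code{c_tilde = min(C, tau - d)} with \code{delta = 1\{C < tau - d\}};
#' the career length F is discarded (right-censored for everyone).
#'
#' @param population output of [simulate_population()].
#' @param design a [study_design()].
#' @return A validated \code{subject_data} object; zero included subjects
#'   yields an empty data.frame with attribute \code{empty = TRUE} rather
#'   than an error.
#' @export
apply_cross_sectional_sampling <- function(population, design) {
  design <- as_study_design(design)
  tau <- design$tau
  keep <- population$d < tau & population$d + population$f > tau
  pop <- population[keep, , drop = FALSE]
  if (nrow(pop) == 0L) {
    out <- data.frame(id = integer(0), cluster = character(0),
                      d = numeric(0), y = integer(0),
                      c_tilde = numeric(0), delta = integer(0))
    attr(out, "empty") <- TRUE
    attr(out, "design") <- design
    return(out)
  }
  df <- data.frame(id = seq_len(nrow(pop)),
                   d = pop$d,
                   y = as.integer(pop$y),
                   c_tilde = pmin(pop$c, tau - pop$d),
                   delta = as.integer(pop$c < tau - pop$d))
  validate_dataset(df, design)
}

#' One simulated survey sample
#'
#' Convenience wrapper: simulate a population, apply the cross-sectional
#' sampling, optionally thin the included subjects to a target size (a
#' calibration knob, off by default), and optionally tag all subjects with
#' a cluster label.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed optional integer seed (set before any draw).
#' @param thin_to optional target number of included subjects; a simple
#'   random subsample is taken when more are included.
#' @param cluster optional single cluster label applied to every subject.
#' @return A validated \code{subject_data} object.
#' @export
simulate_survey <- function(scenario, seed = NULL, thin_to = NULL,
                            cluster = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- apply_cross_sectional_sampling(simulate_population(scenario),
                                        scenario$design)
  if (!is.null(thin_to) && nrow(dat) > thin_to) {
    dat <- dat[sort(sample.int(nrow(dat), thin_to)), , drop = FALSE]
    dat <- validate_dataset(as.data.frame(dat), scenario$design)
  }
  if (!is.null(cluster)) {
    dat$cluster <- as.character(cluster)
  }
  dat
}
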