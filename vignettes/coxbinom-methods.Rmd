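---
title: "Cox-binomial change-point inference: model, simulation world, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cox-binomial change-point inference: model, simulation world, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxbinom)
```

## The data-generating situation

A single cross-sectional survey at calendar time $\tau$ recruits members
of a population in which a *permanent* status change (the motivating case:
consistent condom use by female sex workers) may occur at entry or at any
later time. Each subject reports her entry time $D_i$ and, if the status
has changed, when. The observables are therefore $D_i$, the entry
indicator $Y_i = 1\{C_i = 0\}$, the duration
$\tilde C_i = \min(C_i, \tau - D_i)$ and the event indicator $\delta_i$;
time in view ends at $\tau$, so censoring happens only there, and the
career length $F_i$ is right-censored for *everyone*. Inclusion requires
$D_i < \tau < D_i + F_i$: a prevalent cohort, hence length-biased in $F$.
Under the (untestable) independence of $C$ and $F$, the inclusion event is
independent of $C$ given $D$, so inference on the law of $C$ from the
included sample is valid — the package's validator enforces exactly this
observation scheme, and a simulation test checks the conditional-law
invariance empirically.

## The mixture model and the combined test

The law of $C$ has a point mass at zero and a continuous part, and both
may jump at a known calendar time $t_0 < \tau$:

* $P(Y_i = 1) = \pi_i$, $g(\pi_i) = \beta_0 + \beta_1 x_i$ with
  $x_i = 1\{D_i \ge t_0\}$ (binomial regression, all subjects);
* given $C_i > 0$, a proportional-hazards model on the time-since-entry
  axis, $h_i(t) = h_0(t)\, e^{\gamma z_i(t)}$ with the step covariate
  $z_i(t) = 1\{D_i + t \ge t_0\}$ (Cox regression, $Y_i = 0$ subjects,
  counting-process episodes split at career time $t_0 - D_i$).

The full likelihood factorizes into an ordinary binomial likelihood and a
right-censored survival likelihood, so the parts are fitted separately;
the acceptance suite verifies this factorization against a brute-force
joint maximization (binomial $\times$ discrete-baseline survival
likelihood, all parameters optimized together), which agrees with the
separate fits to far better than the 1e-4 tolerance. Under the null of no
change, the sum of the two 1-df likelihood-ratio (or Wald) statistics is
$\chi^2_2$; with two degrees of freedom the upper tail is the closed form
$p = e^{-Q/2}$. For clustered data both parts carry cluster-sandwich
variances and $Q = \hat\beta_1^2/\hat V_r(\hat\beta_1) +
\hat\gamma^2/\hat V_r(\hat\gamma)$; summing is valid because the two
estimating equations share no parameters and the off-diagonal blocks of
the stacked "meat" vanish, which the tests check by comparing the
subject-clustered sandwich against model-based variances on independent
data.

## Tunable parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `link` (binomial) | `logit` | log link gives prevalence-ratio coefficients but is honestly flagged when it fails to converge near $\pi = 1$ |
| `ties` (Cox) | `efron` | simulated durations are continuous (ties have measure zero); real reconstructed data are year-granular and tie-heavy, where Efron approximates the exact partial likelihood better; Breslow is kept for cross-software checks and for the factorization oracle, whose discrete-baseline profile equals the Breslow partial likelihood |
| `method` (combination) | `lr` | the source of the statistic is stated only as "likelihood ratio (or Wald)"; LR is the default, Wald and the clustered robust Wald `Q` are available |
| `epsilon` (single-Cox) | 1/365.25 yr | the "1 day" imputation for entry acquirers; the estimate is rank-invariant in $\epsilon$ as long as it stays below the smallest genuine duration (warned otherwise) |
| `year_grid` (GEE) | 2000–2008 | four pre and four post intervals around $t_0 = 2004$, bounded by $\tau$; the source gives no grid for simulated data, a symmetric window mirrors the real-data analyses; it is a config knob |
| `alpha` | 0.05 | two-sided, the level used throughout the study being emulated |

Conventions fixed once: time is continuous decimal years on one calendar
axis; "before $t$" in the crude rate $R_t = U_t/N_t$ is strict; an event
or entry exactly at $t_0$ counts as *post* ($z$ and $x$ are
right-continuous). The average slope is the endpoint difference divided by
the span, equivalently the mean of yearly increments — which is what makes
the ceiling artifact visible: with $\mu_{t_0}$ already high, the post
slope cannot exceed $(1-\mu_{t_0})/(\text{last}-t_0)$.

## What the generator emulates — and what it does not

`simulate_population()` reproduces the stated simulation world: 800 women,
birth $\sim N(1973, 7^2)$, entry age $\sim N(22, 4^2)$, career length
$\sim$ Weibull(shape 3, scale 40) with survival
$\exp(-(t/\text{scale})^{\text{shape}})$, entry acquisition Bernoulli
($\pi_1$ before 2004, $\pi_2$ after), and for the rest a
piecewise-exponential duration with hazard $h_1$ before calendar 2004 and
$h_2$ after, sampled by exact inversion. No truncation or rounding is
applied anywhere; negative tails of the normals are kept as drawn (they
are immaterial after the inclusion filter).

One discrepancy is inherited deliberately: with these printed parameters
the included sample is about 670–740 subjects per replicate, whereas the
source reports 350–450 (and 70–290 in the Cox part, versus our 105–610).
We implement the parameters exactly as printed and expose a `thin_to`
subsampling knob (default off) rather than silently altering them. The
consequences are confined to the two GEE-linear power cells, which are
sample-size sensitive and are therefore checked directionally; every
type-I-error cell and the sample-size-robust power cells reproduce within
their Monte-Carlo bands. A green acceptance run therefore establishes
calibration and power of the *methods* under the stated world, not a
reproduction of the historical sample sizes; nor does it say anything
about real data features the generator lacks — recall error in reported
dates, year-granular ties, dependence between $C$ and $F$, survey weights,
or gradual (non-instantaneous) change at $t_0$.

## Numerical and degenerate-input choices

* Crude rates with an empty denominator are `NA`, never an error.
* Non-identifiable parts (all $Y$ equal; no events; $z$ without contrast)
  are flagged, and the combined test falls back to an *explicitly
  downgraded* 1-df test; both parts missing is an error.
* Non-convergence (log-link binomial near $\pi = 1$; saturated GEE-logit
  year cells) is reported as `converged = FALSE` with the diagnostic
  message, and power-study replicates with such fits are excluded from
  the rejection denominator and counted in `na_count`. A year cell at
  proportion 0 or 1 degrades both GEE links (for identity the
  binomial-variance sandwich weights degenerate), a deliberate widening
  of the stated logit-only rule.
* Cluster sandwiches carry no small-sample correction; the $Q$ statistic
  is defined without one. With few clusters (the motivating study has 21)
  the test is accordingly slightly liberal.
* The GEE fit exploits saturation: with one indicator per year, no
  intercept and independence working correlation, the estimating
  equations solve in closed form (yearly proportions, or their logits),
  so no iterative GEE solver is needed; the sandwich is assembled
  directly and verified against a loop-written oracle.
* Replicate seeds are drawn once from the master seed, so study results
  are bit-for-bit reproducible and independent of execution order.

## Known limitations

Known $t_0$ only (no change-point search, whose p-values would not be
$\chi^2$); instantaneous change at $t_0$; no survey weights; no modelling
of the career-length law $F$ (its likelihood factor does not involve the
law of $C$ and is deliberately ignored); no frailty/random-effects Cox
variants. The single-Cox approximation is provided but, as its provenance
flag warns, should not be trusted when the entry-acquirer fraction is
substantial.
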