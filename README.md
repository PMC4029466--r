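# coxbinom

Change-point inference for retrospectively reconstructed status histories:
a mixture of binomial and Cox regression, with the average-slope GEE
comparator and a Monte-Carlo study harness.

## The problem

Large public-health interventions are often scaled up rapidly, with no
baseline data and no control group. One way out is retrospective
reconstruction: survey the target population once, at calendar time τ, and
ask each participant (i) when they entered the population and (ii) whether
— and if so, when — a permanent status change took place. The motivating
study asked female sex workers when they started sex work and since when
they consistently use condoms with occasional clients; the question is
whether the acquisition of consistent condom use changed at the start of
an intervention at a known calendar time t0 (here 1-1-2004, survey at
1-1-2009).

Each subject i contributes entry time D_i, the status-at-entry indicator
Y_i (a point mass at duration zero: some subjects acquire the status the
moment they enter), the observed duration C̃_i = min(C_i, τ − D_i), and
the event indicator δ_i. Inclusion requires being in the population at τ
(D_i < τ < D_i + F_i, career length F_i), a prevalent-cohort scheme that
length-biases F but — under C ⊥ F — leaves inference on C valid.

## The method

The duration C is modelled as a two-part mixture whose both parts may jump
at t0:

* **Binomial part** (all n subjects): P(Y_i = 1) = π_i with
  g(π_i) = β0 + β1·x_i, where x_i = 1{D_i ≥ t0} and g is the logit link
  by default (log, probit, cloglog available).
* **Cox part** (subjects with C > 0): h(t) = h0(t)·exp(γ·z_i(t)) on the
  time-since-entry axis, with the time-dependent step covariate
  z_i(t) = 1{D_i + t ≥ t0}, fitted by partial likelihood in
  counting-process (start, stop] form.

The full likelihood factorizes into the ordinary binomial likelihood and
the survival likelihood, so the two parts are fitted separately and their
likelihood-ratio (or Wald) statistics for β1 = 0 and γ = 0 add to a
statistic that is χ²₂ under the null of no change; for df = 2 the p-value
is exactly exp(−statistic/2). For clustered (multi-district) data, both
parts are refitted with cluster-sandwich variances and
Q = β̂1²/V̂ᵣ(β̂1) + γ̂²/V̂ᵣ(γ̂) is referred to χ²₂ (the cross-blocks of the
stacked sandwich vanish).

The comparator (the average-slope GEE method) expands each subject into a
yearly panel, fits one proportion per calendar year by GEE with identity
(or logit) link and independence working correlation, and tests the
difference in average slope before vs after t0. When rates are already
high before t0 the post slope is bounded above by (1 − μ_t0)/span — the
ceiling artifact that motivates the mixture method.

## Worked example

```r
library(coxbinom)
des <- study_design(t0 = 2004, tau = 2009)
sc  <- scenario_from_levels("Medium", "High", design = des)  # pi 0.5->0.8, h 0.10->0.25
dat <- simulate_survey(sc, seed = 42)   # 690 subjects, 366 acquire at entry

bin <- fit_binomial_part(dat)
cox <- fit_cox_part(dat)
combined_change_test(bin, cox)
#> Combined change-point test (LR): statistic = 44.6817 on 2 df, p = 1.984e-10
#>   components: binomial 22.5125, Cox 22.1692

gf <- fit_yearly_rates_gee(build_panel(dat), "identity")
round(gf$year_coefficients, 3)
#>  2000  2001  2002  2003  2004  2005  2006  2007  2008
#> 0.732 0.747 0.771 0.782 0.802 0.842 0.884 0.898 0.906
average_slope_contrast_test(gf, des)
#> Average-slope contrast: pre 0.0175, post 0.0260, diff 0.0085 (se 0.0056), z = 1.504, p = 0.1326
```

The generator really did change both parts at 2004 (entry-acquisition
probability 0.5 → 0.8, hazard 0.10 → 0.25/year), and the mixture test
rejects overwhelmingly (β̂1 = 1.46, γ̂ = 0.70, p ≈ 2·10⁻¹⁰). The yearly
rates, however, start above 0.73, so the average-slope comparator sees a
post-minus-pre slope difference of only 0.0085/year and cannot reject
(p = 0.13) — the ceiling artifact in action.

A full operating-characteristics table (type-I error and power over the
Low/Medium/High scenario grid, 1000 replicates each):

```r
run_power_study(data.frame(pre = c("Low", "Medium", "High"),
                           post = c("Low", "High", "High")),
                reps = 1000, seed = 1)
```

## Command line

```sh
exec/coxbinom simulate --pre Medium --post High --seed 42 --out subjects.csv
exec/coxbinom fit --data subjects.csv --t0 2004 --tau 2009
exec/coxbinom gee --data subjects.csv --link identity
exec/coxbinom power --scenarios Low/Low,Medium/High --reps 1000 --out power.tsv
```

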