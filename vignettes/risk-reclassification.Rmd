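---
title: "Risk reclassification methods for sickness-absence prognostic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk reclassification methods for sickness-absence prognostic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sareclass)
```

## The question the package answers

Occupational health services want to identify workers at risk of *high
sickness absence* — at least 30 cumulated absence days, or at least 3
absence episodes, in the coming year — so that preventive interventions can
be offered before the absence happens.  Established prognostic models for
these two binary outcomes use age, self-rated health (SRH, a single item
coded poor = 1 to excellent = 4) and prior sickness absence over the two
preceding years.  The package asks, for a candidate new predictor (its
worked case: the 20-item checklist individual strength, CIS, a fatigue sum
score ranging 20–140): *does adding it actually improve who the model
flags?*

Discrimination summaries such as the c-statistic barely move when a modest
predictor joins an adequate model, so the package implements the
reclassification toolkit instead: risk-threshold reclassification tables,
the event/nonevent Net Reclassification Indices, the category-free NRI, the
discrimination slope and the integrated discrimination improvement, plus
Hosmer–Lemeshow calibration testing (reclassification analysis presumes
calibrated models).

## Statistics implemented

Let the *established* model be a logistic regression of the outcome on the
established predictors, and the *extended* model add the new predictor.
Both are maximum-likelihood fits (IRLS, deviance tolerance $10^{-8}$, at
most 100 iterations) and produce per-subject predicted risks $p^{old}_i$,
$p^{new}_i$ in-sample — models are fit and evaluated on the same cohort,
which is the design this literature describes; the in-sample optimism this
induces is why the IDI null behaviour is documented below.

**Reclassification table.** At a risk threshold $t$ each subject is `low`
($p \le t$; the boundary is low, matching the "$\le$ 10% / > 10%" table
convention) or `high`.  Old-category × new-category counts are tabulated
separately for events and nonevents.  Thresholds are analysed
independently (two 2×2 tables at 10% and 20%), not as one three-category
scheme.

**Net Reclassification Index, by stratum.** With `up` = low→high and
`down` = high→low:

$$\mathrm{NRI}_e = P(\mathrm{up}\mid\mathrm{event}) -
  P(\mathrm{down}\mid\mathrm{event}), \qquad
  \mathrm{NRI}_{ne} = P(\mathrm{down}\mid\mathrm{nonevent}) -
  P(\mathrm{up}\mid\mathrm{nonevent}).$$

Each lies in $[-1, 1]$; positive values are improvements.  The overall NRI
is their sum.  When a stratum has no movers the point estimate is 0 but the
result is flagged *not available* ("n.a."), matching how such tables are
published; the 0 is retained internally so sums remain defined.

**NRI inference.**  The standard error of a component is the binomial form

$$\widehat{se} = \sqrt{(\hat p_{up} + \hat p_{down})/n},$$

with symmetric Wald intervals and a two-sided normal p-value, and the
overall SE combined in quadrature.  A variant subtracting
$(\hat p_{up}-\hat p_{down})^2$ inside the root exists; we chose the
unsubtracted form because it is what the classical reclassification
software of this literature computes, and on the package's embedded
reference tables it reproduces the published interval endpoints to the
printed precision (the subtracted variant differs in the second decimal).
For small mover counts both are rough; `bootstrap_ci()` provides a
case/noncase-stratified percentile alternative.

**Category-free NRI.** Any risk increase counts as up, any decrease as
down.  It is computed but always carries a caveat flag: this variant is
known for high false-positive rates and is not interpretable on the
categorical NRI's scale.

**Discrimination slope and IDI.** The slope is
$\bar p_{\mathrm{events}} - \bar p_{\mathrm{nonevents}}$; the IDI is the
slope change between the models, identically equal to
$\overline{\Delta}_{events} + \overline{(-\Delta)}_{nonevents}$ for
per-subject $\Delta = p^{new} - p^{old}$ (the test suite checks this
identity to $10^{-12}$).  Its SE is the two-sample form on the
within-stratum means of $\Delta$.  In-sample, nested MLE fits give a
nonnegative IDI even for a pure-noise predictor — a small positive
optimism; treat small IDIs accordingly.

**Hosmer–Lemeshow.** Subjects are ranked by predicted risk into `groups`
(default 10) near-equal groups — tied risks stay together in the lower
group, the convention consistent with df = groups − 2 = 8 —
and

$$\chi^2 = \sum_g \frac{(O_g - E_g)^2}{n_g \bar\pi_g (1-\bar\pi_g)}$$

is referred to $\chi^2_{groups-2}$.  Groups with $\bar\pi_g \in \{0,1\}$
are skipped with a warning.  Expected counts per group sum exactly to the
summed risks.

## Domain conventions for absence registers

Registers record absence episodes as date intervals from first sick day to
return to work.  Following Dutch insurance convention, two episodes of one
worker with **fewer than 28 days strictly between them** are one episode;
merging is transitive and a gap of exactly 28 days does *not* merge.  The
register holds calendar dates, so the gap is measured in calendar days
(registers do not record which intervening days were worked), with
`min_gap_days` configurable.

Day counts are inclusive of both endpoints (days 1–10 is 10 days) and sum
only the recorded constituents of a merged episode — the worked days inside
a merged gap are not absence days — so day totals are invariant under
merging, and only episode counts change.  Episodes straddling the
observation window are clipped to it before counting.  Outcome labels are
`sa_days >= 30` and `sa_episodes >= 3` over one year of follow-up.
Analyses are complete-case throughout; no imputation.

## The synthetic cohort generator

No individual-level data from the motivating office-worker study can be
shipped, so `generate_cohort()` draws cohorts matching its published
summary statistics; it is the package's test bed and default input.  The
defaults are fixed study conditions, not tuning knobs:

* n = 579; age ~ Normal(44.4, 9.3); 62% men; work hours Normal(34.5, 8.0).
* SRH multinomial with proportions 143/330/103/3 out of 579
  (excellent…poor).
* Fatigue: an integer-rounded truncated normal on [20, 140].  The latent
  mean/SD (37.99, 29.29) were moment-matched once so the *observed*
  truncated distribution has mean 51.2 and SD 21.0; the CIS floor makes it
  right-skewed, as real fatigue scores are.
* Fatigue and SRH are drawn jointly through a Gaussian copula.  The target
  Pearson correlation is −0.44 with the excellent = 4 coding: the source
  study reports $|r| = 0.44$ without a sign convention, and higher fatigue
  must accompany worse self-rated health.  The latent correlation −0.4988
  was calibrated once, numerically, to offset the attenuation caused by
  discretising SRH and truncating fatigue.
* Prior absence days and episodes come from the published 6-bin marginals
  with uniform integer placement within bins (the open-ended bins end at
  150 days and 8 episodes — plausible 2-year accumulations).
* Outcomes are Bernoulli draws from joint logistic models whose slopes are
  the published univariate odds ratios (fatigue 1.16/1.14 per 10 points,
  prior episodes 1.60 per episode, prior days 1.02 per 10 days, SRH
  0.59/0.56 per category, age 0.99/0.92 per 10 years) and whose intercepts
  (−1.4502, −2.1708) were found by `uniroot()` on the simulated mean risk
  at large n so that prevalences hit the published 59/579 and 65/579; the
  calibration is reproducible via `calibrate_intercepts()`.
* Follow-up day/episode *counts* are then drawn consistently with the
  binary labels (30–120 days vs 0–29; 3–6 episodes vs 0–2), with the
  coherence rules that any absence day implies an episode and each episode
  lasts at least a day.
* `missing_rate` plants exactly `round(rate * n)` records with one blanked
  field, to exercise complete-case filtering; outcome fields are blanked in
  pairs so day and episode counts never disagree about missingness.

Using univariate odds ratios as *joint* slopes is a deliberate
simplification: the resulting marginal (univariate) associations shift
where predictors correlate.  Fatigue and SRH are mutually confounded by
construction, so their univariate fits recover the generating values only
approximately, whereas prior absence — generated independently — recovers
its coefficient marginally too, and the joint fit recovers everything.
Recovery tests are therefore asserted against the generating joint
coefficients (±10% relative where $|\log OR| \ge 0.1$; the near-zero age
and prior-days-per-10 coefficients, 0.010 and 0.020 in magnitude, are
asserted at an absolute 0.05 because a relative band below the sampling
standard error at n = 50,000 would be uninformative).

What the generator does **not** emulate: real registers' seasonality and
weekday structure, within-worker correlation between baseline and
follow-up absence, heaping of self-reports, non-participation bias, and
any covariate beyond the published set.  Passing tests show the machinery
is correct under the stated data-generating process, not that fatigue has
any particular added value in other populations.

`generate_register()` inverts `aggregate_register()`: it lays each
worker's merged episodes in the follow-up year with ≥ 28-day separations,
then splits a configurable fraction into two raw episodes with a 1–27-day
internal gap (day totals preserved), so the round trip
`aggregate_register(generate_register(cohort))` reproduces every worker's
follow-up counts exactly while genuinely exercising the merge rule.

## Embedded reference tables

`inst/extdata/reference_tables.json` holds the four published 2×2
reclassification count tables of the motivating study (days/episodes ×
10%/20%).  `verify_reference_tables()` recomputes NRIe/NRIne, their
intervals and p-values, and the reclassified-worker counts from those
counts alone.  Point estimates are compared within one unit of the last
published decimal: from the published counts the 10% NRIe is
3/59 = 5.0847%, printed as 5.09 — an intermediate-rounding artifact of the
original software (the published interval −5.93 to 16.10 is consistent
with 5.0847).  One published p-value (0.04, days at 20%, nonevents)
disagrees slightly with its own published interval; p-values are therefore
compared within ±0.01.  The events p-value printed for the 10% days
threshold equals the z-statistic of its counts and is excluded as a
transcription slip.

## Numerical and design choices

* Thresholds default to 10% and 20% — the data-driven cut-points of the
  motivating study; no clinically established thresholds exist for
  sickness absence.
* Ties at a threshold are `low`; ties in risk share an H–L group (lower).
* Wald inference throughout (symmetric on the log-odds scale for odds
  ratios), matching standard reporting; no profile likelihood.
* Separation in a logistic fit is flagged (`converged = FALSE` plus a
  warning), never returned silently; constant predictors are an error
  naming the column.
* All randomness flows from one explicit integer seed through a private
  RNG stream that restores the caller's `.Random.seed`.
* Test problem sizes: marginal/recovery checks use one cached cohort of
  n = 50,000; Hosmer–Lemeshow size uses 500 replicates of n = 2,000
  (rejection rate asserted in [0.03, 0.08] at α = 0.05); calibration
  across seeds uses 30 cohorts of n = 4,000; oracle-equivalence checks use
  1,000 random instances of n ≤ 50.  These sizes make Monte-Carlo noise
  small relative to every asserted tolerance.

## Limitations

* NRI component inference is asymptotic and fragile with very few movers;
  the "n.a." flag and the bootstrap exist for exactly that reason.
* In-sample risks overstate added value slightly (IDI optimism); a
  held-out design is possible with `predict()` on new data but is not the
  default, to match the analysis the package reproduces.
* The merge rule uses calendar days between episodes, not worked days,
  because registers record calendar intervals only.
* The category-free NRI is reported only with its caveat; it should not be
  used as a headline result.

## A worked run

```{r example, eval = FALSE}
cohort <- add_outcome_labels(generate_cohort(default_params(n = 579, seed = 7)))
fit <- sa_reclass(high_sa_days ~ I(age/10) + srh + I(prior_sa_days/10),
                  data = cohort, add = ~ I(fatigue/10))
summary(fit)
plot(fit)

report <- run_study(study_config(params = default_params(n = 579), seed = 7))
render_report(report, "markdown")

verify_reference_tables()
```
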