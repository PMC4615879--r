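---
title: "Projecting the budget impact of goal-directed fluid therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting the budget impact of goal-directed fluid therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdftroi)
library(dplyr)
```

## The problem

Postoperative complications after major non-cardiac surgery are common —
in large US claims populations more than a third of patients undergoing
procedures such as colectomy, esophagectomy or hip-fracture repair develop
at least one in-hospital complication — and they are expensive: a
complicated admission costs on the order of US$12,000 more than an
uncomplicated one once 30-day readmissions are included. Goal-directed
fluid therapy (GDFT), which titrates perioperative fluids to flow
parameters such as stroke volume, has been shown in meta-analyses of
randomized trials to reduce the odds of postoperative morbidity
(OR 0.77, 95% CI 0.71–0.83). `gdftroi` turns that effect size, together
with observed morbidity and cost figures, into a hospital-level budget
impact: projected complication counts, gross and per-patient cost
savings, return on investment against the cost of monitoring equipment,
and bed-day capacity gains.

The package has two kinds of inputs. **Aggregate ("frame") mode** needs
only printed summary quantities — cohort size $N$, complication count
$C$, mean excess cost $\Delta$, period length $T$ — and reproduces the
projection arithmetic deterministically. **Cohort mode** starts from a
patient-level table (one row per admission with procedure, demographics,
complication flag, cost, length of stay and readmission), from which the
same aggregates are derived, along with descriptive comparisons and a
confounder-adjusted cost model. Because the claims database underlying
the reference estimates is proprietary, the package ships a synthetic
cohort generator whose defaults reproduce the published group- and
procedure-level structure, so the entire patient-level pathway is
testable end to end.

## The projection model

Let $p = C/N$ be the observed morbidity. For an odds-ratio bound
$\mathrm{OR}$, two interpretations are offered (`gdft_effect()`):

* **Count scaling** (default): $C' = \mathrm{round}(C \cdot \mathrm{OR})$.
  This treats the OR as a relative risk. It is the arithmetic of the
  reference analysis and is what reproduces its printed figures, but at
  $p = 0.375$ it overstates the reduction; the package keeps it as the
  default for reproducibility and documents the alternative.
* **Odds transform** (exact for an odds ratio):
  $p' = \mathrm{OR}\,p / (1 - p + \mathrm{OR}\,p)$, $C' =
  \mathrm{round}(N p')$. The two agree as $p \to 0$ (relative difference
  of projected rates below 1% at $p = 0.01$ for any OR in $[0.71, 1]$),
  which the test suite checks by direct computation.

Averted complications $A = C - C'$ convert to money and capacity:

* gross savings $S = A \cdot \Delta$ over the period, $S/T$ per year;
* per-patient savings use the printed-table arithmetic
  $\mathrm{round}(p_{1}\cdot(1-\mathrm{OR})\cdot\Delta)$, where $p_1$ is
  the morbidity rounded to one decimal percent — with the default frame
  ($N = 204{,}680$, $C = 76{,}807$, $\Delta = 11{,}824$) this yields the
  range US\$754–1286. Dividing $S$ by $N$ instead differs by a few
  dollars through rounding (it gives 754–1287); the table arithmetic was
  chosen because it is the convention under which every published
  per-procedure range reproduces exactly;
* bed-days: with a median excess stay $\ell$ (default 3 days) the burden
  is $C\ell$ days; averting $A$ complications recovers $A\ell$ days,
  which at an average stay of $\bar\ell$ (default 5 days) admits
  $\mathrm{round}(A\ell/\bar\ell)$ new patients over the period;
* ROI: per-patient savings divided by the per-patient implementation
  cost (sensor plus monitor amortization,
  $\mathrm{sensor} + \mathrm{price}/(\mathrm{uses/week}\times 52 \times
  \mathrm{years})$; US\$298.08 at the defaults), reported to one
  decimal. Note the upper bound 1286/300 = 4.3 is sometimes quoted
  rounded down to 4 in prose; the package reports 4.3.

**Rounding conventions matter** and are applied exactly where the printed
figures apply them: counts round half-up to integers before any
downstream multiplication (e.g. $13{,}057 \times 3 = 39{,}171$ bed-days;
multiplying the unrounded count does not reproduce the figure), dollar
amounts per patient round half-up to integers, rates to one decimal, and
the new-patients-per-year figure rounds the already-rounded patient
count divided by $T$. Base R's `round()` rounds half to even and would
not reproduce several of these values, so the package uses an explicit
half-up rule throughout. These conventions are asserted against all ten
published per-procedure ranges in the tests.

## The synthetic cohort generator

`simulate_cohort()` emulates the joint structure the published tables
actually constrain — and nothing more:

* per procedure, complication flags are Bernoulli at the printed
  morbidity rate;
* costs are gamma with the printed group mean $m$ and SD $s$
  (shape $(m/s)^2$, scale $s^2/m$), rounded to whole dollars. Gamma was
  chosen because it guarantees positivity, matches the skewness
  assumption of the cost model, and is fully determined by the two
  printed moments. For groups with $s > m$ (e.g. hip-fracture repair)
  the implied shape is below 1 and a small number of draws round to
  zero; these are retained in the cohort and excluded from the gamma GLM
  with a logged count;
* length of stay is log-normal matched to the printed median and IQR
  ($\mu = \ln(\mathrm{median})$, $\sigma = (\ln q_{75} - \ln
  q_{25})/(2 \times 0.6745)$, 0.6745 being the standard-normal upper
  quartile), discretized to whole days with a floor of one;
* 30-day readmission and cost-validity are Bernoulli at the group rates;
  the default invalid-cost rates (4.8% with complications, 0.4%
  without) reproduce the published completeness counts 73,108/76,807 and
  127,398/127,873;
* age is normal truncated at 18 at the group mean/SD, gender and
  elective status Bernoulli, and the Charlson index Poisson at the group
  mean. Only marginals are published, so only marginals are modeled.

A single integer seed drives everything through one substream per
procedure (complication assignment) plus one per procedure-group
(attributes), so a cohort is bit-for-bit reproducible and stable under
partial inspection.

What the generator deliberately does **not** emulate: correlation
between cost, LOS, readmission and comorbidity beyond shared group
membership; hospital-level clustering (the reference population spans
541 centers); and any cost–covariate confounding. Two visible
consequences: the overall LOS median of the simulated "with" group is 6
days rather than the printed 7 (the printed overall row is not a
generation target — the per-procedure medians are, and their mixture has
median 6); and, because no confounding is injected, the adjusted cost
contrast on synthetic data tracks the unadjusted one (≈ US\$11,900)
rather than the published adjusted values (US\$25,390 vs US\$14,841,
difference US\$10,549), which depend on the real covariate joint
distribution and cannot be reconstructed from marginals. Passing
parameter-recovery tests on synthetic data therefore demonstrates the
correctness of the estimation machinery, not the reproduction of the
proprietary cohort's data-dependent results.

## Descriptive comparisons and the adjusted cost model

`summarize_cohort()` mirrors the published table layout: cost statistics
are computed over records with valid cost data only, while LOS and
readmission use all records; quartiles use linear interpolation between
order statistics (R type 7). The two-group comparisons are the field's
standard tests: Welch's $t$ for costs (the group SDs differ by a factor
of ~2.7, so the unequal-variance form is the default, with the pooled
form behind a flag), the Wilcoxon rank-sum with tie correction and
continuity correction for LOS (an exact small-sample method is available
behind a flag and is verified against brute-force enumeration of all
two-group splits up to $n = 10$), and Pearson's chi-squared without
continuity correction for readmission (the correction is immaterial at
claims-database cell sizes and available as a flag). No multiplicity
adjustment is applied across procedures, matching the unadjusted
reporting convention of the source tables.

Costs are adjusted with a gamma GLM with log link — effects are
multiplicative on mean cost — controlling for age, gender, the Charlson
index (continuous), and elective admission, with the procedure category
added in a sensitivity variant. The IRLS deviance tolerance is set to
1e-10, tight enough that the score equations hold to 1e-6 relative
tolerance at the reported fixed point (the suite checks this
orthogonality directly); dispersion is the Pearson statistic over the
residual degrees of freedom; starting values are the responses
themselves, the standard stable choice for gamma/log. Records with
non-positive cost are excluded with a logged count, since the gamma
support is positive. Adjusted group means are classical least-squares
means: predictions on a reference grid with continuous covariates at
their cohort means and categorical covariates averaged with equal
weight over levels, back-transformed through the log link (computed via
`emmeans`).

```{r lsmeans-demo}
co <- simulate_cohort(scale = 0.05, seed = 1)
fit <- fit_cost_glm(co)
tidy(fit, exponentiate = TRUE)
ls_means(fit)
```

## Problem sizes and determinism

The full default cohort (204,680 admissions) generates in a couple of
seconds and is used for the moment-recovery checks; the regular unit
tests run on scaled-down cohorts (0.5–5% of full size, 1,000–10,000
records), which keeps the whole suite under a minute while leaving the
binomial and gamma standard errors tight enough for 3-SE recovery
assertions. GLM parameter recovery uses $n = 20{,}000$ simulated
records with a known injected log-effect, where the 3-SE band is about
±5% on the cost ratio. All stochastic tests fix their seeds; the
pipeline writes byte-identical output bundles for identical
configurations.

## Known limitations

* The effect size is applied uniformly across procedures; no
  procedure-by-effect interaction is modeled (meta-analyses have not
  found one, but the assumption is untestable here).
* The projection assumes complete, instantaneous GDFT implementation;
  no adoption curve is modeled.
* Uncertainty is carried only through the two OR bounds — no bootstrap
  over the cost difference, and no propagation of sampling error in the
  morbidity rates.
* The published gross-savings lower bound ("US\$153 million") does not
  reconstruct exactly from its own inputs ($13{,}057 \times 11{,}824 =
  \mathrm{US\$}154.4$M); the package reports the computed value, and
  per-patient figures — which do reconstruct — are the anchor for
  verification. Similarly, published per-procedure *annualized* savings
  bars use an unstated annualization and are out of scope.
* No reimbursement or profit-margin modeling: freed bed-days are
  reported in days and admissible patients, not revenue.
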