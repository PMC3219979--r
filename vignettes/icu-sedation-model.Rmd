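---
title: "An hourly semi-Markov model of ICU sedation strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An hourly semi-Markov model of ICU sedation strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icusedsim)
```

## The question the model answers

Remifentanil is an ultra-short-acting opioid: it does not accumulate, so
sedation can be lightened quickly and weaning from the ventilator can in
principle start earlier than under conventional regimens built on
morphine or fentanyl with propofol, midazolam or lorazepam. It is also
far more expensive per milligram. Whether a remifentanil-based regimen
(RS) saves money overall therefore depends on whether its higher drug
cost is offset by shorter mechanical ventilation (MV) and a shorter ICU
stay, where a ventilated ICU day costs substantially more than an
unventilated one. `icusedsim` implements a patient-level cost-consequence
model of exactly this trade-off, together with everything needed to feed
and check it: dwell-time estimation from right-censored trial records, a
micro-costing layer, probabilistic sensitivity analysis (PSA), and a
synthetic trial generator with known ground truth.

A modelling approach is needed because trial follow-up of ventilated
patients typically stops at some administrative horizon (here day 10 of
MV) while a sizeable minority of patients is still ventilated then;
parametric survival curves extrapolate beyond that censoring point.

## Model structure

Eight health states describe the patient flow (`health_states()`):
four on the ventilator (1 maintenance, 2 eligible to start weaning,
3 weaning, 4 eligible to extubate), two after extubation (5
post-extubation, 6 eligible for ICU discharge), and two absorbing
states (7 discharged, 8 death). Patients traverse 1 to 7 in order;
death can interrupt anywhere. States 2, 4 and 6 are "eligible" states:
a fraction of patients passes through them instantaneously (a point
mass at zero dwell), the rest stay a Weibull-distributed time.

The model is *semi-Markov* with a one-hour cycle: each state has its own
phase clock, reset to zero on entry, and hour $t$ means the interval
$(t-1, t]$ on that clock. Dwell times follow
$S(t) = \exp[-(Lt)^p]$ with scale $L$ (per hour) and shape $p$
(dimensionless; $p = 1$ is the memoryless exponential), and the hourly
transition probability is the discrete hazard

$$tp(t) = 1 - \frac{S(t)}{S(t-1)},$$

computed as `-expm1(-((Lt)^p - (L(t-1))^p))` for stability. The two
regimens share one model structure with one exception: during
maintenance an RS patient may *switch* to the conventional regimen
(premature discontinuation), after which the patient continues in the
maintenance state under CS dynamics. Death dynamics are pooled across
arms, and all post-extubation dynamics are shared between arms, on the
grounds that once the study drugs are stopped there is no mechanism for
a regimen effect.

### Competing exits within an hour

Up to three causes compete for each hour: death, switch, progression.
The within-cycle resolution is not dictated by the mathematics of the
hazard curves, so the package makes an explicit choice: sequential
conditional Bernoulli draws in the fixed priority order death → switch →
progression. Because hourly probabilities are small, the order is
nearly immaterial; it is documented here and fixed in code
(`build_transition_table()` stores causes in priority order). The
engine actually samples the hour of first exit by inverting the
cumulative distribution implied by this rule — an exact equivalent that
lets whole cohorts be advanced with vectorised arithmetic. Should a
PSA draw push the naive sum of competing hourly probabilities above 1,
the row is renormalised proportionally and a warning is raised; this
keeps every cause represented instead of silently truncating one.

### Horizon

Follow-up is 672 hours (28 days). Patients still in a transient state
at hour 672 are administratively censored; their accrued stay and costs
remain in the means. No half-cycle correction is applied — with
one-hour cycles its effect would be far below the Monte-Carlo noise.

## Estimation from trial records

`estimate_trial_params()` reproduces the estimation conventions of the
emulated study design. For each state and cause, a cause-specific
Weibull is fitted by maximum likelihood in which *exits through any
other cause count as censored at their dwell time* (competing risks as
censoring). Specifically:

* maintenance progression: per arm; maintenance death: pooled across
  arms; time-to-switch: RS only;
* weaning duration: per arm; weaning and post-extubation death: too few
  events for a curve, so constant hourly probabilities
  $1 - \exp(-\text{events}/\text{exposure})$ matched to the observed
  occurrence rate;
* eligible states: the zero-dwell fraction is the observed share of
  exact zeros, per arm for the ventilated states 2 and 4, pooled for
  state 6 (consistent with shared post-extubation dynamics — the
  pooling granularity is a documented choice, as is fitting the
  positive dwells only: the Weibull likelihood is undefined at $t=0$);
* all post-extubation curves: pooled across arms.

The likelihood is maximised on $(\log L, \log p)$ to enforce
positivity, multi-started from the closed-form exponential initialiser
with shapes 0.5, 1 and 2, then polished by Newton steps until the
gradient norm drops below $10^{-8}$. With a fixed shape the scale has
the closed form $\hat L = (n_{ev}/\sum t^p)^{1/p}$, used directly. The
test suite checks the optimiser against an independent iteratively
refined likelihood grid and against `survival::survreg`.

Uncertainty comes from a patient-level bootstrap (default
$B = 1000$; $B$ is not prescribed by the emulated study, so the default
is a documented choice): patients are resampled with replacement,
each Weibull refit, and the empirical SDs of $\hat L$ and $\hat p$ and
their Pearson correlation attached. Resampling is by patient, not by
record, to respect within-patient dependence. Replicates without
events are discarded (an error if more than 10% are).

## Costs

Two components, both at 2006 Dutch hospital price levels, no
discounting over the 28-day horizon:

* **ICU bed**: €2,106 (SE 102) per ventilated day, €1,645 (SE 107) per
  unventilated day, charged per hour as day-cost/24 according to the
  current state.
* **Sedation**: hourly rates derived from mean daily doses times € per
  mg over 24 — before weaning €1.30 (CS) / €7.47 (RS), during weaning
  €0.41 / €3.85. States 1–2 are billed at the before-weaning rate,
  3–4 at the during-weaning rate (the drug-use data distinguish only
  these two phases), nothing after extubation. After a switch the
  patient accrues CS rates from the switch hour onward — the emulated
  study is silent here, but switching regimens implies switching drug
  costs. Recomputing the CS during-weaning rate from the printed dose
  table gives ≈ €0.38 rather than €0.41 (presumably dose rounding in
  the source table); the printed €0.41 is carried as the base-case
  input and the discrepancy is asserted, not hidden, in the tests.

`accumulate_costs()` is exactly additive over any partition of a
history and is cross-checked in the tests against the vectorised
cohort costing used by the engine.

## Cohort simulation and outcomes

`run_cohort()` simulates both arms (default 10,000 patients per arm,
which keeps Monte-Carlo noise in the mean LOS below about 0.05 day) and
reports per arm the mean and median length of stay on MV (hours in
states 1–4 over 24), in the ICU (states 1–6), mean total cost, and the
CS−RS differences. `onlabel_subgroup()` restricts to patients whose
weaning started within 72 hours of model entry (boundary inclusive);
the anchor for "within 72 hours" is model entry, i.e. the start of
maintenance — the natural reading for a licensing window counted from
the start of treatment. The phase clock of a switching patient
continues rather than resets (the alternative would implausibly grant
switchers a fresh maintenance distribution); this too is a documented
choice.

## Probabilistic sensitivity analysis

`run_psa()` redraws every input parameter from its uncertainty
distribution, reruns the cohort, and summarises the replicate
differences with exact order-statistic 95% percentile intervals and
$P(\text{diff} > 0)$ — the probability that the remifentanil regimen
saves. Design choices:

* Each Weibull pair is drawn jointly: $L$ first from its marginal, then
  $p$ from the bivariate-normal conditional given the drawn $L$, using
  the bootstrap correlation. Marginals are normal unless a normal draw
  would put more than 1% of its mass below zero, in which case
  moment-matched lognormals are used with the correlation applied on
  the log scale. Out-of-domain draws are redrawn (at most 100 times).
* Constant death probabilities and zero-dwell fractions are truncated
  normals on their domains; they *are* varied (the emulated analysis
  does not say whether they were — varying them is conservative, and
  because death is pooled its draws shift both arms together).
* The two ICU day costs and four sedation rates are independent
  normals; doses and unit prices are not redrawn separately since the
  hourly-rate SEs already carry the dose uncertainty.
* The inner cohorts (default 2,000 per arm — the outer×inner budget of
  a desk-scale run; raise `n_per_arm` for smoother replicates) use one
  fixed random-number stream across replicates *and* common random
  numbers across arms. Replicate spread therefore reflects parameter
  uncertainty, not patient resampling noise: with all SEs zero every
  replicate is bit-identical, and with structurally identical arms the
  difference distribution is exactly symmetric — both properties are
  asserted in the tests.

## The synthetic trial generator

No individual patient data from the emulated study are available, so
`generate_trial()` produces datasets of the same shape with known
truth: two arms (default 109 conventional, 96 remifentanil), continuous
trajectories drawn from the true parameters, then the trial's
observation rules applied — ventilated phases still ongoing at 240
cumulative MV hours (day 10) are emitted censored and nothing later is
observed for that patient; observation ends at a switch (premature
discontinuation ends data collection); everything stops at 672 hours.
Dose records are drawn per patient from lognormals moment-matched to
the published per-arm dose table. `roundtrip_check()` closes the loop:
generate, estimate, tabulate true versus estimated.

The packaged demonstration truth (`demo_params()`) was calibrated once,
by large-sample simulation, to the published anchors of the emulated
study: about 21% of conventional and 8% of remifentanil patients still
ventilated at day 10, about 11% of remifentanil patients switching
while ventilated, median modelled MV time near 5 days (CS) and 3.7 days
(RS), and a start-of-weaning hazard that is higher under remifentanil
over the first two days and lower from about day three (the curves
cross near hour 71). Within those constraints the split of stay time
between maintenance and weaning, and all downstream dwell parameters,
are plausible round values chosen once; the conventional-arm day-10
tail forces a fat-tailed weaning distribution (shape 0.5) and a CS
median MV time slightly above 5 days — the constraint set is tight and
the medians are treated as a diagnostic, not a target. The attached
standard errors are of the magnitude a patient-level bootstrap yields
at the 109/96 trial size, with the scarce-event curves (death, switch)
tempered to a maximum relative SE of 50% so that sensitivity draws stay
in a sane regime. These are illustrative inputs with known ground
truth, not estimates of any real trial's parameters.

What the generator deliberately does *not* emulate: patient covariates
(severity scores, diagnoses), the 15-centre crossover structure,
inter-centre variation, adverse events (ventilator-associated
pneumonia, ICU-acquired infection, withdrawal syndrome), and any
post-switch data collection. Passing round-trip tests therefore show
that the estimation pipeline is correct under the model's own
assumptions — not that the model is correct for any particular real
ICU population.

## Numerical choices and degenerate inputs

* `hourly_transition_prob()` special-cases $p = 1$ (exactly
  $1 - e^{-L}$ at machine precision) and clamps the cumulative-hazard
  increment at 36 so the result stays strictly below 1 in double
  precision even where the hazard overflows.
* Zero-dwell records are excluded from Weibull fitting; an all-zero
  eligible state is represented as a pure point mass (no Weibull
  component).
* Bootstrap SDs of exactly zero (degenerate data) yield a correlation
  of 0 by convention.
* Percentile intervals use the order statistics at indices
  $\lceil 0.025\,B \rceil$ and $\lceil 0.975\,B \rceil$ — exact,
  reproducible, and directly testable.
* All randomness flows from a single seed per entry point; the same
  seed reproduces results bit for bit.

## Problem sizes used in the test suite

The suite favours closed-form and oracle comparisons at small $n$, and
uses large single runs where a tolerance is statistical: 100,000
patients for the geometric closed-form limit (3 Monte-Carlo SEs),
250,000 per arm for the generator→estimation recovery check — sized so
that the 5% recovery bound sits several sampling SDs out even for the
scarce-event death and switch curves, whose $\hat L$ and $\hat p$ are
strongly correlated under ~90% censoring — and 1,500 replicates for the
PSA symmetry check (binomial error at that size). The demonstration
pipeline is exercised at 5,000 patients per arm.

## Known limitations

The model inherits the emulated study's scope: hospital perspective
only, 2006 Dutch prices, 28-day horizon, no quality-of-life weighting,
no adverse-event pathways, and death curves estimated from scarce
events (their uncertainty dominates some PSA draws). The within-hour
competing-risk order and the switch-clock convention are reasonable
but unverifiable choices; both are isolated behind single functions
should a user want to vary them.
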