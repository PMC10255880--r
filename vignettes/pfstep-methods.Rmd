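---
title: "Methods behind pfstep: cadence banding, agreement, and longitudinal association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pfstep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfstep)
```

This vignette documents the models, conventions and design choices in
`pfstep`: what exactly is computed, which parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and where the numerical edges are.

## Stepping events and cadence bands

The unit of input is a *stepping event*: one contiguous bout of stepping
with a start time, a duration in seconds, and a step count. Cadence
(steps/min) is derived as `steps / (duration / 60)` and is treated as a
continuous quantity throughout.

Quality control removes, in this order:

1. events with fewer than 10 steps — very short bursts give unreliable
   cadence estimates;
2. events with cadence below 20 steps/min or above 175 steps/min — outside
   the range both measurement systems report reliably. The boundaries are
   *kept* (exactly 20 or 175 steps/min passes), since the exclusions are
   phrased as strictly "less than" / "greater than";
3. events starting after the participant's first 7 distinct calendar dates
   (chronological), so that cyclical weekly behaviour cannot distort
   averages. "Days" are wall-clock calendar dates; an event is assigned to
   the date of its start time and events spanning midnight are not split —
   at a daily aggregation scale the bias is negligible and no splitting
   rule is defined for the source data.

An event failing several rules is counted once, under the first rule in
the order above; the exclusion report's counts plus the kept events always
equal the input count.

Daily step counts are then summed in cadence bands:

| band                  | cadence (steps/min)     |
|-----------------------|-------------------------|
| non-walking           | [20, 45)                |
| walking               | [45, 175]               |
| slower-paced walking  | [45, median]            |
| faster-paced walking  | (median, 175]           |
| slower-paced steps    | non-walking + slower-paced walking |

Stepping below 45 steps/min is not considered walking: below that
threshold stepping tends to be unsustained, non-locomotor movement. The
slower/faster split point is the **median walking cadence**: the
unweighted median cadence (each event one vote, regardless of step count)
of all events at or above 45 steps/min, pooled over participants, days and
recording periods. It is population- and device-specific, which is what
makes paired-system comparisons meaningful. Two conventions matter:

- the split uses the *unrounded* median. Rounding the median before
  splitting silently reassigns boundary events; we report a rounded value
  but split on the exact one, with "slower" defined as cadence less than
  or equal to the median.
- the median is unweighted over events rather than step-weighted, because
  the split point is defined as a property of the event distribution.

For longitudinal cohorts the median can be computed pooled over all
periods (default) or from baseline only (`pooled_median` in the pipeline
config); pooling is the default because the split point is meant to be a
stable property of the population and measurement system, not of one
recording wave.

Wear-time validity is protocol-specific and parameterised rather than
hard-coded: a paired-device day is valid when *both* devices were worn at
least 20 h that day; a cohort recording period is valid when the device
was worn at least 18 h/day on at least 6 days of the period. Both
thresholds are inclusive. Wear hours are taken as given input; upstream
non-wear detection is out of scope.

The **pfSTEP biomarker** condenses a period's stepping into two integers:
average slower-paced steps/day and average faster-paced walking steps/day,
rendered `(S; F)`. Their sum must equal the rounded average total steps per
day; when independent rounding of the two components breaks that identity
by one step, the larger component absorbs the difference.

## Agreement: variance-components CCC

Paired daily estimates from a thigh-worn reference system and a wrist-worn
system are modelled as

y_ijk = mu + beta_j + alpha_i + (alpha gamma)_ik + (alpha beta)_ij + e_ijk

with participant i, device j, day k; random effects for participants,
participant x day (shared across devices — both devices observe the same
behavioural day), and participant x device; and a fixed device contrast
beta. The concordance correlation coefficient is

CCC = (s2_subject + s2_subject_day) /
      (s2_subject + s2_subject_day + s2_subject_device + s2_device + s2_error)

where for two devices `s2_device = (beta_wrist − beta_thigh)^2 / 2`. The
numerator contains the variation the two systems should *share*; the
denominator adds the device-specific sources of disagreement. With zero
bias and no device interaction this reduces to the intraclass correlation;
in the balanced single-replicate case with only the subject random effect
it estimates the same quantity as the classical moment-based CCC, which we
use as an independent oracle in the tests.

Estimation choices:

- restricted likelihood by default; negative variance estimates are
  truncated at zero, keeping the CCC in [0, 1];
- a component estimated at the zero boundary (commonly subject x day for
  noisy bands) is retained in the model and reported as 0, not dropped, so
  the CCC formula's terms stay well-defined across bands;
- the four band-specific analyses (total, walking, slower-paced walking,
  faster-paced walking) are independent model fits;
- whether subject x day belongs in a single-period paired design is
  genuinely arguable; it is included by default (days are a real source of
  shared variation) and `random_terms` lets the user drop it.

Confidence intervals are percentile intervals from a **cluster bootstrap**:
participants are resampled with replacement (a resampled participant
enters as a new, distinct cluster) and the model is refitted per replicate
(500 replicates by default). An asymptotic variance-component interval is
fragile at 56 participants, and no closed-form interval is available for
this CCC; bootstrap intervals are therefore the package's method, and
interval widths from other software should not be expected to match
exactly. Replicate refits use the same restricted-likelihood estimator
through a lean code path (the `lme4` deviance function and optimizer
without the full model-object packaging), warm-started at the full-data
estimates; over 20% non-convergent replicates triggers a recorded warning.

## Longitudinal association with physical function

The outcome is the SPPB score (0–12, treated as continuous — the score is
approximately normal in this population), observed at months 0, 6, 12 and
24. Participants must contribute at least two valid periods. Three models
represent stepping, always per 1000 steps:

1. total steps;
2. faster-paced walking steps;
3. faster-paced walking steps + slower-paced steps.

Model 3's two bands are non-overlapping, which keeps the coefficients
interpretable and avoids the collinearity of entering total steps together
with one of its own subsets. All models include categorical time with
baseline reference (the published contrasts are per-time, not linear in
months), allocation and allocation x time (so trial arms can be pooled),
stepping x time interactions, covariates (age — entered linearly, the
natural default absent any stated banding —, sex, site, SF-36 class,
comorbidity, IMD quintile as a factor, education), and a participant
random intercept.

Inference conventions:

- coefficients and 95% CIs come from the restricted-likelihood fit with
  large-sample normal inference (no degrees-of-freedom correction; the
  source analyses do not state one, so exact CI widths are not an
  acceptance surface);
- AIC and log-likelihood come from a full-likelihood refit, because
  restricted-likelihood criteria are not comparable across models that
  differ in fixed effects;
- follow-up stepping coefficients are interaction contrasts relative to
  baseline; `total_effect()` adds the baseline coefficient to the
  interaction to give the total association strength at a time point;
- missing covariates are handled by complete cases; a participant-period
  missing stepping or SPPB is dropped and the participant retained if two
  periods remain;
- sensitivity refits: (i) without the health and socio-economic covariates
  and (ii) per allocation stratum; an ordinal (cumulative-link) check is a
  documented alternative only and is not implemented.

`project_scenario()` is deliberately plain arithmetic —
`delta_slower x theta_slower + delta_faster x theta_faster` in thousands
of steps and SPPB points per 1000 steps, reported to two decimals — so
that published coefficients can be plugged in directly.

## What the simulators emulate

**Paired-device generator** (`paired_sim_config()` defaults): 56
participants x 7 days; latent daily totals from the same crossed
variance-components model the agreement analysis assumes, with mean 9065
steps/day on the thigh system, a +656 steps/day wrist offset, and
components (1.33e7, 9.6e6, 2.6e5, 2.8e6) steps² — an overall daily SD near
5100 with roughly 51% / 37% / 1% shares for subject, day and device
sources. Daily totals are split into bands by a Dirichlet-noised
composition and partitioned into events (each at least 10 steps) whose
cadences follow truncated log-normal mixtures per band; wrist cadences are
shifted +2 steps/min so the two systems' median walking cadences differ.
Wear hours average 22.8 h with a 4% chance of a sub-threshold day, and on
average half an invalid event per participant-day-device is injected
(too-few-steps or out-of-range cadence) so the filters always have work.
Valid events of a day sum *exactly* to the latent daily total, which is
what makes conservation testable. Event durations and per-event step
counts are loosely matched to the described shape of free-living event
distributions, not fitted to data.

**Cohort generator** (`cohort_sim_config()` defaults): 651 participants
over months 0/6/12/24. Per-band stepping is log-normal with a persistent
participant activity factor (60% of log-variance; cross-band correlation)
and period-level noise, calibrated to the published per-period means and
SDs and winsorised at the 99.5th percentile — free-living stepping has
physiological maxima and an unbounded log-normal tail would give single
days implausible leverage. Covariate prevalences follow the published
population structure. SPPB is generated as intercept 8.7 + a gradual
functional decline over follow-up (0/−0.2/−0.4/−0.8) + covariate effects +
allocation x time + per-period stepping effects + participant random
intercept (variance 1.4) + residual (variance 0.5), rounded and clipped to
the 0–12 scale. Two design points deserve emphasis:

- the per-period stepping effects (`theta_*_by_period`) are *effective*
  slopes — defaults 0.03/0.07/0.09/0.16 (slower-paced) and
  0.05/0.27/0.40/0.58 (faster-paced) per 1000 steps, i.e. baseline effects
  plus interaction gains of up to 0.13 and 0.53 at 24 months — so a
  stepping x time model recovers `theta(t) − theta(0)` as the interaction
  coefficient;
- stepping effects act on *deviations from the configured period means*.
  Centring keeps the outcome's location stable across periods so that the
  0–12 clip remains a rarely binding range invariant (~1% of draws)
  rather than a censoring mechanism; slopes are unaffected by centring.
  Without it, the growing stepping effects would push later periods into
  the SPPB ceiling and attenuate exactly the coefficients the simulation
  is meant to recover.

Per-period missingness (6.6%/13.2%/16.4%/22.6%) reproduces the published
per-period sample sizes; in daily detail mode an invalid period receives
fewer than six 18-hour wear days, so the validity rule rediscovers the
generator's missingness draws exactly.

**What the simulators do not emulate** — and hence what passing tests do
not establish about real data: within-week autocorrelation and weekday
structure; seasonal effects; non-wear patterns correlated with behaviour;
device-specific detection failure at low cadences (the generator's device
differences are a clean offset plus independent noise, whereas real wrist
systems misclassify slow stepping in structured ways); informative
missingness; and measurement error in SPPB scoring. The generators
validate the *estimation machinery* under the stated models, not the
models themselves.

## Problem sizes and numerical choices in the test suite

The simulation-based checks run at sizes chosen to balance statistical
resolution against runtime on a single CPU: CCC recovery uses 50
replicates of the 56 x 7 paired design (theoretical CCC 0.90, mean
recovered within ±0.02); bootstrap-interval coverage uses 200 replicates
of a 56-participant x 5-day design with 100 bootstrap resamples each
(nominal 95% interval, empirical coverage checked against [0.90, 0.98] —
a 200-simulation pilot at this scale showed ~0.92); association recovery
uses 100 full-size cohorts, and the null rejection rate 200 cohorts of 250
participants. Exact-arithmetic checks (scenario projections, total
effects, period changes, relative increases) run on the published summary
tables and are tolerance-free.

Degenerate inputs are handled explicitly: zero-variance agreement data
yield CCC 1 with a degenerate interval; an all-zero aggregate yields the
biomarker `(0; 0)`; a zero baseline makes percent change undefined and
flagged rather than infinite; empty event tables filter to empty tables
with zero-count exclusion reports; strata too small to fit are recorded as
skipped with a reason instead of erroring the whole sensitivity suite.

## Known limitations

- The CCC interval is a percentile cluster bootstrap; it slightly
  undercovers below ~40 participants. With very few clusters a
  variance-stabilised or double bootstrap would be preferable.
- The agreement model assumes homoscedastic residuals across devices;
  free-living comparisons often show variance increasing with level, which
  the CCC absorbs but does not model.
- The SPPB is ordinal; the linear treatment matches the primary published
  analysis and is defensible for near-normal scores, but effect sizes near
  the scale limits should be interpreted with the ceiling in mind.
- `total_effect()` sums point estimates; its CI would need the coefficient
  covariance, which is available in the fitted object but not surfaced as
  a combined interval.
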