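---
title: "Methods: risk, survival and mortality estimation in Lynch syndrome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk, survival and mortality estimation in Lynch syndrome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchrisk)
```

## The data and the design

`lynchrisk` analyses prospective surveillance cohorts of carriers of
pathogenic mismatch repair variants (*MLH1*, *MSH2*, *MSH6*, *PMS2*).  A
carrier record holds the gene, sex, a continuous inclusion age (at least
25 years, the age of the first prospectively planned surveillance
examination), a last-observation age, and vital status *at last
observation*.  Cancer events carry an organ code from a controlled
vocabulary (twelve core Lynch-syndrome sites plus breast, skin and other,
which are carried through the machinery but flagged non-LS) and a timing
class: `previous`/`prevalent` (at or before inclusion) or `prospective`
(strictly after inclusion, not after last observation).

Event scoring is organ-wise: a previous or prevalent cancer in an organ
makes the carrier ineligible for that organ (no person-time, no events);
otherwise the first prospective tumour in the organ is the scored event
and later or synchronous same-organ tumours are discarded.  Cancers in
other organs never affect an organ's eligibility.  Scoring is idempotent.
Two deliberate conventions: a diagnosis at exactly the last-observation
age is accepted (diagnosis at final contact is a common registry
pattern), and two same-organ tumours at the same age count once while two
different organs at the same age both count (organs are analysed
independently).

## Incidence

Carriers contribute exact fractional person-years per half-open five-year
band `[25,30), ..., [70,75)`, from `max(inclusion, 25)` to
`min(first scored event in the organ set, last observation, 75)`.  Left
truncation is built in: time before inclusion contributes nothing, and
risk is set to zero at age 25.  An event at exactly 75 falls outside the
grid.  The annual incidence rate per band is `AIR = d / PY`; undefined
(and flagged `NA`) when a band has no person-time.

Cumulative incidence uses the person-time Nelson–Aalen transform,

$$H(a) = \sum_{i: \text{band} \le a} \mathrm{AIR}_i\, w_i, \qquad
  Q(a) = 1 - e^{-H(a)},$$

with band widths `w_i = 5`.  Treating band counts as Poisson given the
person-time gives `var H(a) = sum w_i^2 d_i / PY_i^2`; the squared width
matters — each band's rate enters `H` with weight `w_i`, so its variance
enters with `w_i^2` (omitting it understates the variance 25-fold on a
five-year grid, which the parameter-recovery experiment below would
detect immediately).  The 95% interval is log-normal on the hazard scale,
`H exp(±1.96 sqrt(var H)/H)`, mapped through `1 − exp(−·)`, which keeps
`0 ≤ ci_low ≤ Q ≤ ci_high ≤ 1` by monotonicity.  At ages where no events
have accumulated the interval is the exact Poisson zero-event bound
`[0, 1 − exp(−3/PY)]` (the "rule of three"); at the age-25 anchor, where
person-time is zero by construction, it is `[0, 0]`.  A band with events
but no person-time is an error.  Whether the originating analyses used
the log-transformed or a plain Wald interval is not documented; the
log-normal form is standard practice and is isolated in one place so it
can be swapped.  Printed registry confidence intervals are therefore not
claimed to be reproduced digit by digit.

Organ groups (colorectum, endometrium+ovary, all LS organs) are analysed
like single sites: eligibility requires no prevalent cancer in *any*
member, and risk time stops at the first event in any member.  The group
curve satisfies `max_organ Q ≤ Q_group ≤ sum_organ Q` — but only
asymptotically.  In expectation the group hazard equals the summed organ
hazards, so the sum bound's margin is just the concavity slack of
`1 − exp` (about `Q_a Q_b`), while the group and organ analyses run on
slightly different risk sets; at young ages the margin (~1e-4) is smaller
than the correlated Monte-Carlo noise, and strict violations of order
1e-4 occur with appreciable probability in any implementation.  The
bounds are therefore asserted at the lifetime age (75), where the margin
dominates, and that is also the scale on which published group overlaps
(e.g. colon + rectum vs colorectal) are compared.

## Survival after cancer and mortality

Crude overall survival after a first prospective cancer in an organ
diagnosed before 65 uses the Nelson–Aalen cumulative death hazard,
`S(t) = exp(−H_NA(t))`, with death from any cause as the event and
censoring at last observation.  Tied deaths and censorings are resolved
deaths-first (the censored subject is still at risk), the conservative
standard convention.  Carriers with a later cancer in another organ stay
in the risk set: the quantity is crude, not cause-specific.  `S5`/`S10`
are step-function readouts (last value carried forward), with
delta-method standard errors.  Genes are pooled by default; per-gene
curves are available (`by_gene = TRUE`).  An adjustment hook (`adjust`)
is provided for diagnosis-correction schemes such as surveillance
overdiagnosis corrections; no such correction is applied by default
because no specific scheme is defined here — the hook is deliberately a
no-op.

Crude mortality to age 75 is the product `M75 = Q(65) × (1 − S10)`: the
probability of developing the cancer by 65 times the probability of dying
within ten years of it.  It is an empirical crude quantity — no
competing-risk decomposition — and is displayed as an integer percent
rounded half away from zero, the only convention consistent with every
published cell (1.59 → 2, 0.999 → 1, 0.459 → 0).  No confidence interval
is propagated onto `M75` itself; the incidence interval is reported
alongside, as in the published tables.

## Median age of onset

The conditional risk `c(a) = Q(a)/Q(75)` conditions on developing the
cancer by 75 (lifetime risk approximated by the risk at 75).  The median
onset age is the first age at which the piecewise-linear interpolant of
`c` over the grid reaches 50%.  The conditional CI curves
(`ci/Q(75)`, truncated to `[0, 1]`) are interpolated the same way; the
lower CI age is the crossing of the conditional *upper* curve and vice
versa.  Numerical conventions: a curve that never reaches 50% yields
`NA`, as does one already at or above 50% at its first informative age
("always above"); when the interpolant touches 50% along a flat segment
the left endpoint is reported; `Q(75) = 0` yields an all-`NA` estimate.
The age-25 anchor is excluded from the CI curves (its interval is
degenerate `[0,0]` because person-time at 25 is zero by construction, so
including it would force a crossing through an artefactual point); the
point-estimate curve keeps its zero anchor.

## Deaths by cancer type

The death table counts, per organ and gene, carriers with a scored
prospective cancer and how many were dead at last observation.  A carrier
who died after cancers in two organs appears in both rows — semantics are
per cancer type, not per carrier — and shares are taken over the column
sum of deaths in the organ set.  These column-sum semantics are the only
ones consistent with the published share arithmetic (e.g. colorectal
deaths 76 of 209 = 36%).

## The simulator and what passing tests mean

`simulate_cohort()` draws, per carrier: gene and sex from mixing
proportions; inclusion age from a normal truncated at 25 (gene-specific
means 42.5/43.6/48.3/49.9 years, matching the reported cohort means; the
spread, sd 12 years, is our choice — only means are reported); censoring
from an exponential with rate 0.125/year capped at an administrative
cutoff of 80 years, giving a mean follow-up of about 8 years; and one
latent cancer age per organ by exact inverse-CDF sampling of the
piecewise-constant hazard over 25–75 (analytic per band, no rejection).
Organs are independent latent failure times; the death clock starts at
the earliest prospective cancer only, with an exponential organ-specific
hazard — this matches the crude (cause-ignoring) survival target, not a
full competing-risks system.  Latent cancers falling before inclusion are
recorded as prevalent cancers and block their organ, exactly as the
scoring rules expect; with `prevalent = FALSE` the draws are conditioned
on no event before inclusion instead.  Both constructions leave the
post-inclusion hazard equal to the model hazard, so the left-truncated
estimators are consistent either way.  A single seeded RNG stream with a
fixed iteration order gives byte-identical cohorts per seed; records are
generated in carrier order, so reproducibility is per-configuration, not
invariant under reordering of an existing file.

The default hazard table is the reference scenario used throughout the
tests: *MLH1* carriers with a colon hazard rising from 0.002 to
0.016/year (cumulative risk ≈30% at 65, comparable to the registry's
colon estimates) and a constant stomach hazard of 0.001/year, with death
hazards reproducing 87% and 63% ten-year survival.  Closed-form ground
truth (`ground_truth()`) gives `Q*(a) = 1 − exp(−Σ λ_i w_i)`,
`S10* = exp(−10 μ)`, `M75* = Q*(65)(1 − S10*)`.

What the simulator does *not* emulate: surveillance effects on incidence
(the hazards are "as-surveilled" hazards, as in the registry whose
carriers are all under colonoscopy), centre or country heterogeneity,
time trends in treatment, cause-specific death, and dependence between
organ-specific latent times beyond the shared death clock.  Passing the
recovery tests therefore shows the estimators are correct for the stated
sampling model, not that registry data meet that model.

## Test calibration and problem sizes

The calibration experiment runs 20 seeded replicates of the reference
scenario at n = 20,000 carriers and requires the pipeline's `Q(65)`,
`S10` and `M75` for colon to fall within three estimated standard errors
of the closed-form truth in at least 19 of 20; with correct variances the
per-replicate failure probability is well under 5%.  Person-year
arithmetic is checked against an independent day-resolution counter
(1,000 random small cohorts; per-carrier totals within 1/365
person-year), median-onset interpolation against a 0.001-year grid scan
(500 random curves, agreement to 0.01 years), and `exp(−H_NA) ≥ S_KM`
against `survival::survfit` on simulated risk sets.  Smaller cohorts
(400–8,000) back the structural property tests; these sizes were chosen
so the full suite represents each property at meaningful precision.

## Known limitations

- Confidence intervals follow standard Nelson–Aalen/Poisson practice but
  cannot be certified against the originating registry software.
- `M75` carries no propagated interval.
- Carriers included above 75 are accepted but contribute nothing to the
  25–75 grid; no extrapolation beyond 75 is attempted.
- The overdiagnosis adjustment hook is intentionally inert.
- Median-onset `NA` semantics at the "always above 50%" edge depend on
  excluding the degenerate age-25 CI anchor, as documented above.
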