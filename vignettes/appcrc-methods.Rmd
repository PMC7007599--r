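---
title: "Methods: app-based capture-recapture for hidden-population size and migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: app-based capture-recapture for hidden-population size and migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appcrc)
```

## The problem

Key populations for HIV surveillance — here men who have sex with men
(MSM) — lack population-level denominators: census instruments do not
enumerate them, and survey-based estimates cover single cities at best.
Geosocial networking apps offer a different route: app users can be
enumerated nationwide by querying "nearby users" from virtual positions
laid out on a regular grid, and repeated enumeration turns the app into a
two-sample capture-mark-recapture experiment. `appcrc` implements that
entire chain — enumeration, estimation, inequality and similarity
statistics, and holiday-vs-nonholiday migration flows — together with a
synthetic-population generator with known ground truth, so every stage can
be validated without access to any proprietary app data.

## Estimation model

### Two-sample capture-recapture

Two enumeration windows, months apart, each record the set of distinct user
IDs seen. With `m` users in the first window, `n` in the second and `k`
in both, the closed-population size of the app-using population is
estimated by the bias-reduced (Chapman) form of the Lincoln–Petersen
estimator:

$$\hat N_{sn} = \frac{(m+1)(n+1)}{k+1} - 1 .$$

Its assumptions are the classical ones: a closed population (no entries or
exits between the windows), independent samples, and equal capture
probability across individuals. `lincoln_petersen()` evaluates the formula
in full double precision; `k = 0` is admitted with a warning because the
estimate is then effectively unbounded.

For uncertainty we use the Chapman variance

$$\widehat{\mathrm{Var}} = \frac{(m+1)(n+1)(m-k)(n-k)}{(k+1)^2(k+2)},$$

with a normal-approximation 95% interval
$\hat N_{sn} \pm 1.96\sqrt{\widehat{\mathrm{Var}}}$. The published estimates
come with symmetric CIs whose construction is unstated; the Chapman
variance with a normal approximation is the simplest method consistent
with that shape and is our documented choice. Exact reproduction of
published CI bounds is therefore not claimed anywhere in the package.

### Internet-penetration multiplier

Not every member of the target population uses the app. Each provincial
app-user estimate is scaled to the whole population by dividing by the
province's internet-penetration fraction $\pi_i$, taken as a known
constant:

$$\hat N_i = \hat N_{sn,i} / \pi_i .$$

CI bounds are divided by the same constant, i.e. penetration contributes
no variance. This mirrors the deterministic division behind the published
table and keeps the national variance a simple sum of stratum variances
scaled by $1/\pi_i^2$ (independent strata).

### Rounding

All person counts are rounded half away from zero (`round_half_away()`),
stated once and reused everywhere. Provincial estimates are rounded for
reporting, but the national total is the rounded **sum of the unrounded
provincial quotients**. This matters at the last digit: the 31 published
provincial integers sum to one less than the published national total,
while the unrounded quotients sum to it exactly — so aggregation on the
unrounded scale is the only convention that reproduces both the provincial
integers and the national total, and it is the one we adopt.

## Enumeration protocol

`build_grid()` lays a square lattice (default spacing 5 km) over the study box; cells are half-open
intervals $[x, x+s)\times[y, y+s)$ so each point belongs to exactly one
cell. `mask_uninhabited()` removes cells with no residents — our stand-in
for masking by a nighttime-light population layer. `nearby_query()`
returns the `K` nearest online users from a cell centre (planar Euclidean
distance; at desk scale no geodesic math is warranted), nearest first,
ties broken by user ID; `enumerate_day()` unions the per-cell queries and
deduplicates.

The app's true list length is not public; we default to `K = 60` (a
typical page limit) but expose it everywhere, and the pipeline's default
is complete coverage (`K = Inf`), matching the implicit assumption that a sufficiently dense enumeration
recovers every online user. Truncation
undercount is therefore explored as a *property* (capture sets are
monotone in `K`; at `K` at least the online count the enumeration equals
the true online set) rather than calibrated to any reported figure.

## The synthetic population

`generate_population()` creates a closed population of agents per the
configuration:

* **Stratum sizes are exact**: province $i$ receives
  `round(adult_men[i] * msm_prevalence[i])` agents, so ground truth is an
  assertable function of the configuration, not a random variable.
* **App adoption** is Bernoulli with probability equal to provincial
  internet penetration — exactly the assumption the multiplier inverts, so
  the demo pipeline tests the full inferential loop.
* **Daily online behaviour** is Bernoulli per agent-day. The daily
  probability is either constant (used by default in tests, satisfying
  equal catchability) or drawn per agent from a Beta distribution
  (default shapes 2 and 6, mean 0.25) to let users study
  equal-catchability violations. No public data describe the true daily
  activity distribution of app users; the Beta default is an explicit
  stand-in.
* **Migration**: exactly `round(migrant_fraction * n)` agents receive a
  work province different from home, with destination probability
  proportional to the candidate provinces' adult-male counts — mirroring
  the observed drift toward populous, developed provinces. Agents sit in
  their home province during the holiday window and in their work province
  otherwise, which is precisely the operational definition of origin and
  destination used downstream.
* **Geography** is abstract: province centroids on a jittered planar
  lattice, agents scattered around the occupied centroid with an isotropic
  Gaussian (default SD 30 km). No real shapes, rasters or distances are
  emulated.

What the generator deliberately does **not** emulate: open populations
(churn between the capture windows), correlated day-to-day activity,
tourism during holidays (every move is "migration"), sub-provincial
structure, and device- or profile-level artefacts of real app scraping.
Passing tests therefore validate the estimator and pipeline logic under
the model's assumptions; they do not validate those assumptions for any
real data source.

## Statistics

* `gini()` — Lorenz-curve Gini, optionally weighted. The published Gini
  of MSM among adult men comes with no stated weighting; we expose the
  adult-men-weighted form and the unweighted form, and treat neither
  published value as reproducible (the full provincial daily inputs are
  unpublished).
* `geodetector_q()` — the geographical-detector statistic
  $q = 1 - \sum_h N_h\sigma_h^2 / (N\sigma^2)$ with population variances,
  the convention of the original geodetector literature.
* `pattern_similarity()` — comparing two continuous spatial patterns
  with q requires turning one of them into a stratification, and no
  published rule says how. Our
  adapter discretizes the first pattern into `n_strata` equal-size
  quantile classes (ties resolved by rank; default 5 classes) and
  evaluates q of the second pattern over those classes, with a
  permutation p-value (default 999 shuffles) as the significance
  substitute. Under the null the expected q is about
  $(n_{strata}-1)/(n-1)$, which the tests verify.
* `share_of_total()` and `coefficient_of_variation()` report at the
  2-decimal and population-SD conventions of the published tables; the
  sample-SD variant is exposed because the published SD convention is
  unstated.

## Migration flows

A user observed in both periods contributes one origin–destination pair:
origin = holiday province, destination = nonholiday province. A user seen
in several provinces within one period is assigned the *modal* province
over observed days, ties broken by earliest observation date, then by
name — a deterministic rule covering an otherwise under-specified
assignment, stated once in `assign_period_province()`.
`build_od_matrix()` cross-tabulates the pairs; its margins are conserved
by construction and checked in tests. The flow threshold familiar from published flow maps (flows of at least
1500) is a reporting filter
(`destination_shares(min_flow = )`), never applied to the matrix itself.

## Pipeline and reproducibility

`run_pipeline()` composes simulate → enumerate → estimate → stats →
migrate with per-stage toggles. Every stochastic stage derives its seed
from the configuration seed, so a configuration determines the whole
report bundle byte for byte; for that reason the written manifest records
the seed, package version and per-stage record counts but **no
timestamps**. Capture-sample strata tie a recaptured user to the province
of first capture, mirroring physical marking.

## Problem sizes

The bundled demonstration study uses 10 provinces, about 50,000 agents,
a 20% migrant share, constant daily online probability 0.25 and 5/7/7-day
windows; estimator-recovery checks use a population of 10,000 with capture
probability 0.3 in 1,000 replicates, and the end-to-end recovery check
averages 20 independent pipeline replicates. These sizes give stable
percent-level statistics (binomial SEs well under the tolerances tested)
while keeping a full run interactive.

## Known limitations

* The penetration multiplier assumes app adoption equals internet
  penetration within every province; any differential adoption biases the
  adjusted totals proportionally.
* The normal-approximation CI can undercover for small strata or low
  recapture counts; coverage is verified only in the tested regimes.
* Migration and holiday travel are indistinguishable in two-snapshot
  origin–destination data.
* The geodetector similarity depends on the (documented) quantile
  stratification; other stratifications give other q values.
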