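---
title: "Age-stage, two-sex life table methods in agestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage, two-sex life table methods in agestage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The model

`agestage` analyzes cohorts of individually followed arthropods censused
every 24 h from oviposition to death. The age-stage, two-sex framework keeps
both sexes and every developmental stage in the bookkeeping, so individuals
that develop at different speeds, die before adulthood, or never reproduce
all contribute to the population parameters — unlike female-only age-specific
life tables, which discard males and development-rate variation.

Conventions used throughout, chosen once and asserted by the test suite:

* **Age.** Age 0 is the day of oviposition; the daily census maps to unit
  age classes. An individual with `death_age` $D$ is alive on census days
  $0, \dots, D-1$.
* **Schedules.** $s_{xj}$ is the probability that a fresh egg is alive and
  in stage $j$ at age $x$ — an empirical multiple of $1/N$. The adult stage
  is split by sex. $l_x = \sum_j s_{xj}$, and
  $m_x = \sum_j s_{xj} f_{xj} / l_x$ where $f_{xj}$ is mean daily eggs per
  occupant of $(x, j)$ (nonzero only for adult females).
* **Net reproductive rate.** $R_0 = \sum_x l_x m_x$. Because both routes
  count the same eggs, $R_0 = F \cdot N_f / N$ exactly, where $F$ is mean
  eggs per female; the suite checks the two independent computations agree
  to $10^{-9}$ on every cohort.
* **Euler–Lotka.** $\sum_x e^{-r(x+1)} l_x m_x = 1$ with age indexed from
  0. The $(x+1)$ exponent is deliberate and prominent: the off-by-one
  alternative moves $r$ in the third decimal on realistic schedules.
* **Derived rates.** $\lambda = e^r$ and $T = \ln(R_0)/r$ by construction.
* **Life expectancy.** $e_{xj}$ is the mean of `death_age` $- x$ over the
  individuals empirically observed in $(x, j)$; no parametric transition
  model is fitted. Hence $e_{0,\text{egg}}$ equals the cohort mean lifespan,
  deaths included.
* **Reproductive value.** $v_{xj} = \frac{e^{r(x+1)}}{s_{xj}} \sum_{i \ge x}
  e^{-r(i+1)} \sum_y s'_{iy} f_{iy}$, with $s'$ the occupancy of later ages
  conditional on being in $(x, j)$, again taken from the empirical
  trajectories. At the origin $v_{0,\text{egg}} = \lambda$, a consequence of
  the Euler–Lotka equation that the suite asserts on every reproducing
  cohort.

Individuals dying inside a stage contribute their partial days in that stage
to $s_{xj}$ and $e_{xj}$, but stage-duration means use completers only —
this is what makes survivor counts in duration tables differ from the cohort
size. Males brought in from stock colonies to form or replace couples are
stored with `excluded = TRUE` and never analyzed.

## Numerical choices

* **Root finding.** $r$ is found by bracketed bisection on $[-5, 5]$
  followed by Newton polishing with the analytic derivative; the returned
  root satisfies the Euler–Lotka residual $< 10^{-12}$ (default `tol`).
  Ages with $l_x m_x = 0$ are dropped from the sum first, since
  $e^{-rx}$ overflows at the bracket ends for long-lived cohorts.
* **Degenerate cases.** $R_0 = 0$ (a diet on which nothing reproduces)
  raises a classed condition that [demographic_parameters()] and the report
  functions convert to `NA` — the zero-reproduction treatment is a first
  class citizen, not an error path. $m_x$ is defined as 0 where $l_x = 0$.
  $T$ is `NA` when $r = 0$.
* **Bootstrap.** The resampling unit is the individual: $N$ draws with
  replacement per replicate, every statistic recomputed from scratch
  (including $r$, by re-solving Euler–Lotka on the resampled schedule).
  Confidence intervals are plain percentile intervals — no bias correction
  is applied, matching the stated comparison rule of the original
  procedure, which bases significance on the 95% CI of differences.
  Replicates on which a statistic is undefined (e.g. an all-male resample)
  are skipped and counted, with a warning above 1% of `B`; skipping is the
  least biased default and the count keeps it auditable. Arms of a paired
  test are resampled independently, each on its own seed substream
  (`seed`, `seed + 1`); whether the original software pairs resamples by
  index is not documented, and independent arms are the conservative
  choice. The design default is `B = 100000`; the package's own tests run
  at `B` between 400 and 50,000 to stay desk-scale.
* **Letters.** The compact letter display is derived from the pairwise
  significance matrix by enumerating maximal cliques of the
  "not-different" relation (exact for the handful of treatments such
  studies compare): treatments share a letter exactly when they do not
  differ.

## The synthetic cohort generator

`preset_config()` encodes the four prey-diet study designs of the
motivating experiment — 50-egg cohorts, the egg → L1 → … → pupa → adult
sequence, stage-specific mortality (including the diet on which every larva
dies in the fourth instar), sex ratio, APOP, per-female fecundity and
per-sex adult longevity — with every target equal to the published cohort
statistic. Design choices, in decreasing order of consequence:

* **Duration distributions.** Integer days drawn as
  $\lfloor m \rfloor + \mathrm{Bern}(m - \lfloor m \rfloor) +
  \mathrm{round}(\mathcal N(0, \sigma_j))$, with $\sigma_j$ topping the
  variance up to $(\mathrm{SE}\sqrt n)^2$ from the printed SEs. The mean is
  exact by construction; rounding a continuous deviate (e.g. a discretized
  gamma) would bias stage means by up to ~0.1 d, which parameter-recovery
  checks at 300 cohorts would detect immediately. Where the printed SE is
  0.0 the duration is constant.
* **Fecundity curve.** Each female's daily expected laying follows a
  discretized asymmetric triangle anchored at the mean total
  pre-oviposition period, with width $2F/h$ fixed by the lifetime total
  $F$ and the observed peak daily rate $h$, and the peak age identified
  from the published intrinsic rate by deterministic Euler–Lotka inversion
  of the expected schedule. The raw daily fecundity curves were not
  deposited, and their printed late "peak day" is the maximum of a ragged
  empirical curve, not its center of mass: a triangle peaked there is
  *inconsistent* with the published $r$ and $T$ (it implies $r \approx
  0.099$ where 0.126 is printed). Anchoring the shape on the demographic
  parameters reproduces $r$, $T$, $R_0$, $F$ and the peak height; the
  cost, documented here deliberately, is that the simulated curve peaks
  earlier (about day 31–38) than the raw curves' noisy maxima.
* **Laying pattern.** A female's lifetime total (normal, SD from the
  printed SE, floored at 1) is allocated multinomially over an
  intermittent subset of her laying window, so mean fecundity is recovered
  exactly even when death truncates the window. The first laying day — the
  day her APOP completes — always carries an egg, because that is what
  defines APOP in the census. APOP is redrawn for the rare female whose
  drawn longevity would end before it, so every female lays, as in the
  published data where the fecundity and APOP tables share the same female
  counts.
* **Longevity.** The published sex-specific longevities are read as
  *adult* (post-emergence) lifespans. This reading makes the published
  table internally consistent: combining them with immature durations and
  pre-adult death ages reproduces the published egg-to-death total
  longevity (e.g. $107.0$ vs $107.1$ d for the two-spotted-mite diet).
  The summary therefore reports both conventions, explicitly labelled.
* **Death timing.** Deaths within a stage occur at a uniformly drawn day
  inside the drawn stage duration; within-stage death timing is not
  reported in such studies.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: durations are sex-blind (the published 0.1-d
male/female difference is ignored); daily clutch sizes are multinomial
rather than biologically clustered, so realized oviposition-day counts run
~10% below target on the long-window diets; fecundity is independent of
longevity apart from truncation; and there is no diet-switch model — the
complementary diet-switch cohort exists only as a printed-count fixture.

## Problem sizes

The test suite simulates 300 cohorts of $n = 50$ per preset for parameter
recovery (grand means within 2 Monte-Carlo SEs of the configured targets,
with disjoint seed blocks per preset), 500 null repetitions at
`B = 1000` for the paired-test type-I rate, 300 repetitions at `B = 400`
for CI coverage, and `B = 50000` for the closed-form SE comparison; oracle
equivalence uses brute-force per-day scans on cohorts of at most 10
individuals. These sizes keep the whole suite around a minute on one core
while leaving Monte-Carlo error well below the tolerances tested.

## Worked example

```{r example, eval = FALSE}
cfg <- preset_config("m_persicae")
coh <- simulate_cohort(cfg, seed = 1)
sched <- build_schedule(coh)
demographic_parameters(sched)
cohort_summary(coh)
bootstrap_lifetable(coh, "r", B = 2000, seed = 1)
compare_treatments(
  list(m_persicae = coh,
       t_ogmophallos = simulate_cohort(preset_config("t_ogmophallos"), seed = 2)),
  "fecundity", B = 2000, seed = 3)
```

## Known limitations

Bootstrap SEs of published tables cannot be reproduced exactly — they
depend on the undeposited raw individual records — so the suite validates
the bootstrap against closed forms and simulated truth instead. The
percentile CI undercovers slightly at very small female counts (a known
property of percentile intervals), which is why coverage is checked against
a binomial band rather than equality. The compact-letter clique enumeration
is exponential in the number of treatments and guarded at 12; studies of
this design compare 3–4.
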