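# agestage

Age-stage, two-sex life table analysis for arthropod rearing cohorts.

## The problem

Prey-suitability and host-quality studies in biological control follow a
cohort of individually reared predators (typically 50 eggs per diet) with a
daily census from oviposition to death, recording stage transitions, sex at
adult emergence, and daily egg counts of females. Classical female-only
age-specific life tables discard the males and the variation in development
rate among individuals, which biases the population parameters. The
age-stage, two-sex framework keeps both sexes and all stages in the
bookkeeping, and `agestage` implements it end to end for users who want the
analysis scriptable and reproducible in R: ecologists and biocontrol
researchers comparing diets, temperatures or host plants by demographic
performance.

## The model

From the per-individual trajectories the package tabulates the age-stage
survival rate *s<sub>xj</sub>* (probability a fresh egg is alive and in
stage *j* at age *x*, adults split by sex) and the fecundity schedule
*f<sub>xj</sub>*, and derives

- *l<sub>x</sub>* = Σ<sub>j</sub> *s<sub>xj</sub>*, *m<sub>x</sub>* =
  Σ<sub>j</sub> *s<sub>xj</sub> f<sub>xj</sub>* / *l<sub>x</sub>*
- net reproductive rate *R*₀ = Σ *l<sub>x</sub> m<sub>x</sub>*
  (= *F·N<sub>f</sub>/N* exactly)
- intrinsic rate of increase *r* solving the Euler–Lotka equation
  Σ<sub>x</sub> e<sup>−r(x+1)</sup> *l<sub>x</sub> m<sub>x</sub>* = 1
  (age indexed from 0)
- finite rate λ = e<sup>r</sup> and mean generation time *T* = ln *R*₀ / *r*
- age-stage life expectancy *e<sub>xj</sub>* and reproductive value
  *v<sub>xj</sub>* from the empirical trajectories

plus the cohort statistics (stage durations, pre-adult survival, sex ratio,
APOP, TPOP, oviposition days, fecundity, longevities), bootstrap SEs and
percentile CIs for all of them (resampling unit = individual, statistics
recomputed per replicate), and paired bootstrap tests between treatments
with compact letter displays. A synthetic cohort generator reproduces the
statistical structure of a four-diet predator study — including a diet with
100% pre-pupal mortality, whose *R*₀ = 0 / undefined-*r* path is handled as
a first-class case — so the whole pipeline is testable without raw data.

## Worked example

```r
library(agestage)
coh <- simulate_cohort(preset_config("m_persicae"), seed = 1)
coh
#> <cohort> treatment 'm_persicae': 50 individuals (0 excluded)
#>   stages: egg > L1 > L2 > L3 > L4 > prepupa > pupa > adult
#>   reached adult: 48 (24 female / 24 male); egg records: 761

sched <- build_schedule(coh)
str(demographic_parameters(sched))
#> List of 4
#>  $ R0    : num 219
#>  $ r     : num 0.126
#>  $ lambda: num 1.13
#>  $ T     : num 42.8

bootstrap_lifetable(coh, "r", B = 2000, seed = 1)
#> <boot_result> r ('m_persicae'): 0.1258, SE 0.0044, 95% CI [0.1161, 0.1335]
#>   B = 2000, degenerate = 0, seed = 1

compare_treatments(
  list(m_persicae = coh,
       t_ogmophallos = simulate_cohort(preset_config("t_ogmophallos"), seed = 2)),
  "fecundity", B = 2000, seed = 3)
#> <treatment_comparison> fecundity (B = 2000):
#>      treatment estimate letter
#>     m_persicae 455.8333      a
#>  t_ogmophallos  22.1875      b
```

Reading the output: this simulated aphid-diet cohort grows at *r* ≈ 0.126
per day (λ ≈ 1.13: 13% daily multiplication), each initial egg yields
*R*₀ ≈ 219 eggs of the next generation over a ≈ 43-day generation, and the
bootstrap SE on *r* (0.004) matches the scale such studies report. The
comparison assigns different letters: mean fecundity differs between the
diets at the 95% level of the paired bootstrap test.

`run_analyze()`, `run_compare()` and `run_simulate()` write the summary
table, parameter estimates with bootstrap CIs, and tidy curve CSVs
(*s<sub>xj</sub>*, *l<sub>x</sub>*, *m<sub>x</sub>*, *f<sub>xj</sub>*,
*e<sub>xj</sub>*, *v<sub>xj</sub>*); `inst/scripts/agestage-cli.R` exposes
them as `analyze` / `compare` / `simulate` subcommands.

See `vignettes/two-sex-lifetable-methods.Rmd` for the model conventions,
numerical choices and what the synthetic generator does and does not
emulate.

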