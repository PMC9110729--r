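Package: agestage
Title: Age-Stage, Two-Sex Life Table Analysis for Arthropod Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age-stage, two-sex life tables from per-individual cohort
    life-history records (daily census of stage transitions, survival and
    fecundity). Computes age-stage specific survival (s_xj), age-specific
    survival (l_x) and fecundity (m_x), stage-specific fecundity (f_xj), net
    reproductive rate (R0), intrinsic rate of increase (r) by solution of the
    Euler-Lotka equation, finite rate of increase (lambda), mean generation
    time (T), age-stage life expectancy (e_xj) and reproductive value (v_xj).
    Provides bootstrap standard errors and percentile confidence intervals for
    every statistic, paired bootstrap tests between treatments with compact
    letter displays, a documented CSV interchange format, and a synthetic
    cohort generator for predator prey-suitability study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
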