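test_that("APOP and TPOP follow the emergence / first-egg definitions", {
  stages <- default_stage_ontology()
  # single female emerging at day 18 and first laying at day 25
  ind <- data.frame(id = "f1", treatment = "toy", excluded = FALSE,
                    sex = "female", death_stage = "adult", death_age = 40,
                    stringsAsFactors = FALSE)
  durs <- c(3, 2, 2, 3, 4, 1, 3, 22) # immature sums to 18
  for (j in seq_along(stages)) ind[[stages[j]]] <- durs[j]
  fec <- data.frame(id = "f1", age_day = c(25, 27), eggs = c(4, 2),
                    stringsAsFactors = FALSE)
  s <- cohort_summary(cohort(ind, fec, treatment = "toy"))
  expect_equal(s$apop$mean, 7)
  expect_equal(s$tpop$mean, 25)
  expect_equal(s$oviposition_days$mean, 2)
  expect_equal(s$fecundity$mean, 6)
})

test_that("TPOP decomposes exactly into immature duration plus APOP", {
  for (tr in c("t_urticae", "t_ogmophallos", "m_persicae")) {
    s <- cohort_summary(fixture_cohort(tr))
    expect_equal(s$tpop$mean, s$immature_female$mean + s$apop$mean,
                 tolerance = 1e-12)
  }
  cfg <- preset_config("m_persicae")
  s <- cohort_summary(simulate_cohort(cfg, seed = 11))
  expect_equal(s$tpop$mean, s$immature_female$mean + s$apop$mean,
               tolerance = 1e-12)
})

test_that("sex ratio reproduces the published survivor counts", {
  expect_equal(round(cohort_summary(fixture_cohort("t_urticae"))$sex_ratio$mean,
                     2), 0.52)
  og <- cohort_summary(fixture_cohort("t_ogmophallos"))
  expect_equal(og$n_females, 17L)
  expect_equal(og$n_males, 20L)
  expect_equal(round(og$sex_ratio$mean, 2), 0.46)
})

test_that("reproductive statistics are NA (not zero) when no female laid", {
  s <- cohort_summary(fixture_cohort("t_evansi_switch"))
  expect_true(is.na(s$apop$mean) && is.na(s$tpop$mean))
  expect_identical(s$apop$n, 0L)
  # fecundity over females that laid nothing is 0, with n = number of females
  expect_equal(s$fecundity$mean, 0)
  ev <- cohort_summary(fixture_cohort("t_evansi"))
  expect_true(is.na(ev$sex_ratio$mean))
  expect_equal(ev$preadult_survival$mean, 0)
})

test_that("stage duration means use completers only", {
  tab <- stage_duration_table(fixture_cohort("t_urticae"))
  # the two pupal deaths spent days in the pupa but did not complete it
  expect_identical(tab$n[tab$stage == "pupa"], 48L)
  expect_identical(tab$n[tab$stage == "L4"], 50L)
  # larva-adult composite: L1..pupa sum per individual reaching adulthood
  stages <- default_stage_ontology()
  ind <- data.frame(id = "a", treatment = "toy", excluded = FALSE,
                    sex = "male", death_stage = "adult", death_age = 21,
                    stringsAsFactors = FALSE)
  durs <- c(3, 2, 3, 3, 4, 1, 4, 1)
  for (j in seq_along(stages)) ind[[stages[j]]] <- durs[j]
  tab2 <- stage_duration_table(cohort(ind, treatment = "toy"))
  expect_equal(tab2$mean[tab2$stage == "larva_adult"], 17)
})

test_that("descriptive SE equals sd/sqrt(n) computed directly", {
  set.seed(408)
  coh <- random_cohort(n = 9)
  tab <- stage_duration_table(coh)
  ind <- coh$individuals
  death_idx <- match(ind$death_stage, coh$stages)
  for (k in seq_len(nrow(tab) - 1)) {
    vals <- ind[[tab$stage[k]]][death_idx > k]
    if (length(vals) > 1) {
      expect_equal(tab$se[k], stats::sd(vals) / sqrt(length(vals)),
                   tolerance = 1e-12)
    }
  }
})

test_that("total-longevity mean equals life expectancy at the origin", {
  for (tr in c("t_urticae", "t_ogmophallos")) {
    coh <- fixture_cohort(tr)
    s <- cohort_summary(coh)
    e <- life_expectancy(build_schedule(coh))
    expect_equal(s$longevity_total$mean, unname(e[1, "egg"]),
                 tolerance = 1e-12)
  }
})

test_that("both longevity conventions are reported and differ by immature time", {
  s <- cohort_summary(fixture_cohort("t_urticae"))
  expect_equal(s$longevity_female_total$mean - s$longevity_female_adult$mean,
               s$immature_female$mean, tolerance = 1e-12)
})

test_that("the flat summary table carries one labelled row per statistic", {
  df <- as.data.frame(cohort_summary(fixture_cohort("m_persicae")))
  # 7 immature stages + larva_adult composite + 13 scalar statistics
  expect_identical(nrow(df), 21L)
  expect_true(all(nzchar(df$definition)))
  expect_equal(df$mean[df$statistic == "fecundity"], 467.6)
})
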