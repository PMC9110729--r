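test_that("a small individuals table builds a validated cohort", {
  stages <- default_stage_ontology()
  ind <- data.frame(
    id = c("a", "b", "c"), treatment = "toy", excluded = FALSE,
    sex = c("undetermined", "female", "male"),
    death_stage = c("egg", "adult", "adult"),
    death_age = c(2, 20, 18), stringsAsFactors = FALSE)
  durs <- list(a = c(2, rep(NA, 7)), b = c(3, 2, 2, 2, 3, 1, 2, 5),
               c = c(2, 2, 2, 2, 3, 1, 2, 4))
  for (j in seq_along(stages)) {
    ind[[stages[j]]] <- vapply(durs, `[`, numeric(1), j)
  }
  coh <- cohort(ind, treatment = "toy")
  expect_s3_class(coh, "cohort")
  expect_identical(cohort_size(coh), 3L)
})

test_that("validation rejects malformed records with informative errors", {
  base <- fixture_cohort("t_urticae")
  # skipped stage: remove an intermediate duration
  bad <- base
  bad$individuals$L2[1] <- NA
  expect_error(validate_cohort(bad), class = "agestage_validation_error")
  # death_age inconsistent with stage durations
  bad <- base
  bad$individuals$death_age[1] <- bad$individuals$death_age[1] + 1
  expect_error(validate_cohort(bad), "death_age",
               class = "agestage_validation_error")
  # fecundity recorded for a male
  bad <- base
  bad$fecundity$id[1] <- "m01"
  expect_error(validate_cohort(bad), "non-female",
               class = "agestage_validation_error")
  # unsexed adult
  bad <- base
  bad$individuals$sex[1] <- "undetermined"
  expect_error(validate_cohort(bad), "sexed",
               class = "agestage_validation_error")
})

test_that("the stored spider-mite cohort file matches its published counts", {
  path <- system.file("extdata", "urticae_counts.csv", package = "agestage")
  coh <- read_cohort(path)
  ind <- coh$individuals
  expect_identical(nrow(ind), 50L)
  adults <- ind$death_stage == "adult"
  expect_identical(sum(adults), 48L)
  expect_identical(sum(ind$sex == "female" & adults), 25L)
  expect_identical(sum(ind$sex == "male" & adults), 23L)
})

test_that("missing required columns raise a format error with the file name", {
  path <- system.file("extdata", "urticae_counts.csv", package = "agestage")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sex <- NULL
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  expect_error(read_cohort(tmp), "sex", class = "agestage_format_error")
})

test_that("write-read roundtrip is the identity on the data model", {
  coh <- fixture_cohort("m_persicae")
  d1 <- file.path(tempdir(), "rt1.csv")
  d2 <- file.path(tempdir(), "rt2.csv")
  write_cohort(coh, d1)
  again <- read_cohort(d1)
  write_cohort(again, d2)
  expect_identical(readLines(d1), readLines(d2))
  expect_identical(readLines(sub("\\.csv$", "_fecundity.csv", d1)),
                   readLines(sub("\\.csv$", "_fecundity.csv", d2)))
  # per-stage survivor counts preserved
  stages <- coh$stages
  for (s in stages) {
    expect_identical(sum(!is.na(again$individuals[[s]])),
                     sum(!is.na(coh$individuals[[s]])))
  }
})

test_that("an empty cohort writes a header-only file", {
  stages <- default_stage_ontology()
  ind <- data.frame(id = character(), treatment = character(),
                    excluded = logical(), sex = character(),
                    death_stage = character(), death_age = numeric(),
                    stringsAsFactors = FALSE)
  for (s in stages) ind[[s]] <- numeric()
  coh <- cohort(ind, treatment = "empty")
  tmp <- tempfile(fileext = ".csv")
  write_cohort(coh, tmp)
  expect_identical(length(readLines(tmp)), 1L)
})

test_that("survivor count at a stage equals a brute-force scan", {
  set.seed(401)
  for (rep in 1:5) {
    coh <- random_cohort()
    ind <- coh$individuals
    for (s in coh$stages) {
      expect_identical(sum(!is.na(ind[[s]])),
                       sum(vapply(seq_len(nrow(ind)), function(i)
                         !is.na(ind[[s]][i]), logical(1))))
    }
  }
})

test_that("excluded individuals never contribute to any statistic", {
  coh <- fixture_cohort("t_urticae")
  extra <- coh$individuals[coh$individuals$id == "m01", ]
  extra$id <- "stock_male"
  extra$excluded <- TRUE
  coh2 <- cohort(rbind(coh$individuals, extra), coh$fecundity,
                 treatment = coh$treatment)
  expect_identical(cohort_size(coh2), 50L)
  expect_identical(cohort_size(coh2, excluded = TRUE), 51L)
  s1 <- cohort_summary(coh)
  s2 <- cohort_summary(coh2)
  expect_equal(s2$fecundity$mean, s1$fecundity$mean)
  expect_equal(s2$sex_ratio$mean, s1$sex_ratio$mean)
  expect_equal(build_schedule(coh2)$l_x, build_schedule(coh)$l_x)
})
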