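# Bootstrap SEs, paired tests and the compact letter display.

test_that("the study-design default resample count is 100,000", {
  expect_equal(eval(formals(bootstrap_lifetable)$B), 100000L)
  expect_equal(eval(formals(paired_bootstrap_test)$B), 100000L)
})

test_that("a cohort of identical individuals bootstraps to SE = 0", {
  stages <- default_stage_ontology()
  ind <- do.call(rbind, lapply(1:6, function(i) {
    row <- data.frame(id = sprintf("i%d", i), treatment = "toy",
                      excluded = FALSE, sex = "female",
                      death_stage = "adult", death_age = 20,
                      stringsAsFactors = FALSE)
    durs <- c(3, 2, 2, 2, 3, 1, 2, 5)
    for (j in seq_along(stages)) row[[stages[j]]] <- durs[j]
    row
  }))
  fec <- data.frame(id = sprintf("i%d", 1:6), age_day = 16, eggs = 10,
                    stringsAsFactors = FALSE)
  coh <- cohort(ind, fec, treatment = "toy")
  for (st in c("fecundity", "R0", "r", "longevity_total")) {
    br <- bootstrap_lifetable(coh, st, B = 50, seed = 1)
    expect_equal(br$se, 0, info = st)
    expect_equal(br$ci[1], br$ci[2], info = st)
  }
})

test_that("bootstrap SE of a mean approaches the closed form s/sqrt(n)", {
  coh <- fixture_cohort("t_urticae")
  d <- coh$individuals$death_age
  br <- bootstrap_lifetable(coh, "longevity_total", B = 4000, seed = 2)
  target <- stats::sd(d) / sqrt(length(d)) * sqrt((length(d) - 1) / length(d))
  expect_lt(abs(br$se - target) / target, 0.10)
})

test_that("identical seeds give bit-identical bootstrap results", {
  coh <- fixture_cohort("t_ogmophallos")
  b1 <- bootstrap_lifetable(coh, "r", B = 300, seed = 42)
  b2 <- bootstrap_lifetable(coh, "r", B = 300, seed = 42)
  expect_identical(b1$values, b2$values)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_lifetable(coh, "r", B = 300, seed = 43)
  expect_false(identical(b1$values, b3$values))
})

test_that("degenerate replicates are skipped, counted and warned about", {
  # 2 females among 6 individuals: all-male resamples make r undefined
  stages <- default_stage_ontology()
  ind <- do.call(rbind, lapply(1:6, function(i) {
    row <- data.frame(id = sprintf("i%d", i), treatment = "toy",
                      excluded = FALSE,
                      sex = if (i <= 2) "female" else "male",
                      death_stage = "adult", death_age = 20 + i,
                      stringsAsFactors = FALSE)
    durs <- c(3, 2, 2, 2, 3, 1, 2, 5 + i)
    for (j in seq_along(stages)) row[[stages[j]]] <- durs[j]
    row
  }))
  fec <- data.frame(id = c("i1", "i2"), age_day = 16, eggs = c(8, 12),
                    stringsAsFactors = FALSE)
  coh <- cohort(ind, fec, treatment = "toy")
  expect_warning(br <- bootstrap_lifetable(coh, "r", B = 400, seed = 3),
                 "degenerate")
  expect_gt(br$degenerate, 0)
  expect_identical(br$degenerate + sum(!is.na(br$values)), 400L)
})

test_that("a statistic undefined on the full cohort is an error", {
  expect_error(bootstrap_lifetable(fixture_cohort("t_evansi"), "r", B = 10),
               class = "agestage_validation_error")
})

test_that("a cohort compared with itself on the same stream is never significant", {
  coh <- fixture_cohort("t_urticae")
  res <- paired_bootstrap_test(coh, coh, "fecundity", B = 200,
                               arm_seeds = c(7, 7))
  expect_false(res$significant)
  expect_equal(res$ci, c(0, 0))
})

test_that("a published-scale fecundity contrast is significant at B = 2000", {
  res <- paired_bootstrap_test(fixture_cohort("t_urticae"),
                               fixture_cohort("t_ogmophallos"),
                               "fecundity", B = 2000, seed = 9)
  expect_true(res$significant)
  expect_gt(res$ci[1], 0)
})

test_that("type-I error of the paired test is near nominal under the null", {
  cfg <- null_config()
  set.seed(409)
  n_rep <- 120
  hits <- vapply(seq_len(n_rep), function(i) {
    a <- simulate_cohort(cfg, seed = 20000 + 2 * i)
    b <- simulate_cohort(cfg, seed = 20001 + 2 * i)
    paired_bootstrap_test(a, b, "fecundity", B = 400,
                          arm_seeds = c(2 * i, 2 * i + 1))$significant
  }, logical(1))
  rate <- mean(hits)
  # 3 binomial SEs around 0.05 at this repetition count
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("percentile CIs cover the configured truth at a near-nominal rate", {
  cfg <- null_config()
  n_rep <- 300
  covered <- vapply(seq_len(n_rep), function(i) {
    coh <- simulate_cohort(cfg, seed = 30000 + i)
    br <- bootstrap_lifetable(coh, "fecundity", B = 400, seed = i)
    br$ci[1] <= 100 && 100 <= br$ci[2]
  }, logical(1))
  rate <- mean(covered)
  expect_lt(abs(rate - 0.95), 3 * sqrt(0.95 * 0.05 / n_rep))
})

test_that("letter displays follow the pairwise significance pattern", {
  u <- fixture_cohort("t_urticae")
  o <- fixture_cohort("t_ogmophallos")
  p <- fixture_cohort("m_persicae")
  cmp <- compare_treatments(list(urt = u, ogm = o, per = p), "fecundity",
                            B = 600, seed = 5)
  tab <- cmp$table
  sig <- cmp$significant
  for (i in 1:2) {
    for (j in (i + 1):3) {
      ti <- tab$treatment[i]; tj <- tab$treatment[j]
      share <- length(intersect(strsplit(tab$letter[i], "")[[1]],
                                strsplit(tab$letter[j], "")[[1]])) > 0
      expect_identical(share, !sig[ti, tj])
    }
  }
  # self-comparison on shared streams collapses to a single letter
  cmp2 <- compare_treatments(list(a = u, b = u), "fecundity", B = 200,
                             seed = 5)
  expect_identical(unique(cmp2$table$letter), "a")
})
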