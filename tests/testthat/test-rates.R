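# Demographic parameters: R0, r, lambda, T, e_xj, v_xj.

single_pulse_cohort <- function(eggs = 1) {
  # one female laying `eggs` eggs on one day -> l_x m_x concentrated at one age
  stages <- default_stage_ontology()
  ind <- data.frame(id = "f1", treatment = "pulse", excluded = FALSE,
                    sex = "female", death_stage = "adult", death_age = 15,
                    stringsAsFactors = FALSE)
  durs <- c(2, 1, 1, 1, 2, 1, 2, 5)
  for (j in seq_along(stages)) ind[[stages[j]]] <- durs[j]
  fec <- data.frame(id = "f1", age_day = 12, eggs = eggs,
                    stringsAsFactors = FALSE)
  cohort(ind, fec, treatment = "pulse")
}

test_that("R0 is zero without reproduction and total-eggs/N with it", {
  expect_equal(net_reproductive_rate(build_schedule(fixture_cohort("t_evansi"))), 0)
  set.seed(403)
  for (rep in 1:8) {
    coh <- random_cohort()
    sched <- build_schedule(coh)
    expect_equal(net_reproductive_rate(sched), oracle_R0(coh),
                 tolerance = 1e-12)
  }
})

test_that("R0 satisfies the two-sex identity F * N_f / N", {
  for (tr in c("t_urticae", "t_ogmophallos", "m_persicae")) {
    coh <- fixture_cohort(tr)
    s <- cohort_summary(coh)
    expect_equal(net_reproductive_rate(build_schedule(coh)),
                 s$fecundity$mean * s$n_females / s$N, tolerance = 1e-9)
  }
})

test_that("a unit reproduction pulse gives r = 0 and lambda = 1", {
  sched <- build_schedule(single_pulse_cohort(eggs = 1))
  expect_equal(net_reproductive_rate(sched), 1)
  r <- intrinsic_rate(sched)
  expect_equal(r, 0, tolerance = 1e-10)
  expect_equal(finite_rate(0), 1)
})

test_that("the Euler-Lotka solution matches an independent root-finder", {
  set.seed(404)
  done <- 0
  while (done < 8) {
    coh <- random_cohort()
    sched <- build_schedule(coh)
    if (net_reproductive_rate(sched) <= 0) next
    done <- done + 1
    r <- intrinsic_rate(sched)
    oc <- oracle_census(coh)
    expect_equal(r, oracle_r(oc$l_x, oc$m_x), tolerance = 1e-10)
    # residual below tolerance and sign of r consistent with R0
    lxmx <- sched$l_x * sched$m_x
    resid <- abs(sum(exp(-r * (sched$ages + 1)) * lxmx) - 1)
    expect_lt(resid, 1e-12)
    expect_identical(r > 0, net_reproductive_rate(sched) > 1)
  }
})

test_that("zero-reproduction cohorts report rates as undefined, not crash", {
  sched <- build_schedule(fixture_cohort("t_evansi"))
  expect_error(intrinsic_rate(sched), class = "agestage_undefined_rate_error")
  pars <- demographic_parameters(sched)
  expect_equal(pars$R0, 0)
  expect_true(is.na(pars$r) && is.na(pars$lambda) && is.na(pars$T))
  # life expectancy is still computable
  e <- life_expectancy(sched)
  expect_false(anyNA(e[1, 1]))
})

test_that("generation time follows ln(R0)/r and is undefined at r = 0", {
  expect_equal(mean_generation_time(exp(2 * 0.1), 0.1), 2)
  expect_warning(expect_true(is.na(mean_generation_time(1, 0))))
})

test_that("life expectancy at age 0 equals mean observed lifespan", {
  # everyone lives exactly 10 days
  stages <- default_stage_ontology()
  ind <- do.call(rbind, lapply(1:4, function(i) {
    row <- data.frame(id = paste0("i", i), treatment = "toy",
                      excluded = FALSE, sex = "undetermined",
                      death_stage = "L1", death_age = 10,
                      stringsAsFactors = FALSE)
    for (s in stages)

      row[[s]] <- switch(s, egg = 4, L1 = 6, NA_real_)
    row
  }))
  sched <- build_schedule(cohort(ind, treatment = "toy"))
  expect_equal(life_expectancy(sched)[1, "egg"], c(egg = 10))
  set.seed(405)
  for (rep in 1:6) {
    coh <- random_cohort()
    sched <- build_schedule(coh)
    e <- life_expectancy(sched)
    expect_equal(unname(e[1, "egg"]),
                 mean(coh$individuals$death_age), tolerance = 1e-12)
  }
})

test_that("life expectancy matrix matches the naive per-cell oracle", {
  set.seed(406)
  coh <- random_cohort(n = 8)
  sched <- build_schedule(coh)
  e <- life_expectancy(sched)
  oc <- oracle_census(coh)
  for (x in sched$ages) {
    for (j in sched$stages) {
      expect_equal(unname(e[x + 1, j]), oracle_exj(oc, x, j),
                   tolerance = 1e-12)
    }
  }
})

test_that("reproductive value equals lambda at the origin and the explicit sum", {
  set.seed(407)
  done <- 0
  while (done < 5) {
    coh <- random_cohort()
    sched <- build_schedule(coh)
    if (net_reproductive_rate(sched) <= 0) next
    done <- done + 1
    r <- intrinsic_rate(sched)
    v <- reproductive_value(sched, r)
    expect_equal(unname(v[1, "egg"]), exp(r), tolerance = 1e-9)
    oc <- oracle_census(coh)
    for (x in sched$ages[seq_len(min(6, length(sched$ages)))]) {
      for (j in sched$stages) {
        expect_equal(unname(v[x + 1, j]), oracle_vxj(oc, x, j, r),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("reproductive value rises with age toward a single fecundity pulse", {
  coh <- single_pulse_cohort(eggs = 4)
  sched <- build_schedule(coh)
  r <- intrinsic_rate(sched)
  v <- reproductive_value(sched, r)
  # the lone individual's v along its trajectory grows until the laying age
  traj <- vapply(0:12, function(x) {
    stage <- sched$stages[sched$occupancy[1, x + 1]]
    v[x + 1, stage]
  }, numeric(1))
  expect_true(all(diff(traj) > 0))
})
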