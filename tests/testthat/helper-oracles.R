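# Brute-force oracles, independent of the package's vectorized
# implementations: everything here is computed by naive per-individual,
# per-day scans and explicit sums.

# Random small cohort: 3..10 individuals with arbitrary stage-of-death,
# random integer durations, random fecundity for females.
random_cohort <- function(n = sample(3:10, 1), p_fec = 0.85,
                          treatment = "random") {
  stages <- default_stage_ontology()
  rows <- list()
  fec <- list()
  for (i in seq_len(n)) {
    k <- sample(seq_along(stages), 1)
    durs <- sample(1:4, k, replace = TRUE)
    is_adult <- k == length(stages)
    sex <- if (is_adult) sample(c("female", "male"), 1) else "undetermined"
    row <- data.frame(id = sprintf("i%02d", i), treatment = treatment,
                      excluded = FALSE, sex = sex,
                      death_stage = stages[k], death_age = sum(durs),
                      stringsAsFactors = FALSE)
    for (j in seq_along(stages)) {
      row[[stages[j]]] <- if (j <= k) durs[j] else NA_real_
    }
    rows[[i]] <- row
    if (is_adult && sex == "female" && stats::runif(1) < p_fec) {
      emergence <- sum(durs[-k])
      alive_ages <- emergence:(sum(durs) - 1)
      n_days <- sample.int(length(alive_ages), 1)
      days <- sort(alive_ages[sample.int(length(alive_ages), n_days)])
      fec[[length(fec) + 1]] <- data.frame(
        id = sprintf("i%02d", i), age_day = days,
        eggs = sample(1:5, n_days, replace = TRUE), stringsAsFactors = FALSE)
    }
  }
  cohort(do.call(rbind, rows), if (length(fec)) do.call(rbind, fec) else NULL,
         treatment = treatment, stages = stages)
}

# Per-individual day list: age -> schedule stage name ("dead" past death).
oracle_daylist <- function(ind_row, stages, x_max) {
  adult <- stages[length(stages)]
  entered <- stages[!is.na(unlist(ind_row[stages]))]
  labels <- unlist(lapply(entered, function(s) {
    lab <- if (s == adult) paste0(adult, "_", ind_row$sex) else s
    rep(lab, ind_row[[s]])
  }))
  c(labels, rep("dead", x_max + 1 - length(labels)))
}

# Naive census: counts of individuals per (age, schedule stage), egg totals
# per age, and the derived l_x, m_x, f_x(female) — all by daily scan.
oracle_census <- function(coh) {
  ind <- coh$individuals[!coh$individuals$excluded, , drop = FALSE]
  stages <- coh$stages
  adult <- stages[length(stages)]
  sched_stages <- c(stages[-length(stages)],
                    paste0(adult, "_female"), paste0(adult, "_male"))
  N <- nrow(ind)
  x_max <- max(ind$death_age) - 1
  counts <- matrix(0, nrow = x_max + 1, ncol = length(sched_stages),
                   dimnames = list(NULL, sched_stages))
  daylists <- lapply(seq_len(N), function(i)
    oracle_daylist(ind[i, ], stages, x_max))
  for (dl in daylists) {
    for (x in 0:x_max) {
      st <- dl[x + 1]
      if (st != "dead") counts[x + 1, st] <- counts[x + 1, st] + 1
    }
  }
  eggs_age <- rep(0, x_max + 1)
  fec <- coh$fecundity[coh$fecundity$id %in% ind$id, , drop = FALSE]
  for (k in seq_len(nrow(fec))) {
    eggs_age[fec$age_day[k] + 1] <- eggs_age[fec$age_day[k] + 1] + fec$eggs[k]
  }
  l_x <- rowSums(counts) / N
  fem <- counts[, paste0(adult, "_female")]
  f_fem <- ifelse(fem > 0, eggs_age / fem, 0)
  m_x <- ifelse(l_x > 0, (eggs_age / N) / l_x, 0)
  list(counts = counts, N = N, l_x = l_x, m_x = m_x, f_fem = f_fem,
       eggs_age = eggs_age, daylists = daylists,
       death_age = ind$death_age, sched_stages = sched_stages)
}

# Total eggs / N by direct summation over individuals.
oracle_R0 <- function(coh) {
  ind <- coh$individuals[!coh$individuals$excluded, , drop = FALSE]
  fec <- coh$fecundity[coh$fecundity$id %in% ind$id, , drop = FALSE]
  sum(fec$eggs) / nrow(ind)
}

# Independent root-finder for the Euler-Lotka equation.
oracle_r <- function(l_x, m_x) {
  lxmx <- l_x * m_x
  pos <- lxmx > 0
  f <- function(r) sum(exp(-r * (which(pos))) * lxmx[pos]) - 1
  stats::uniroot(f, c(-2, 2), tol = 1e-13, extendInt = "downX")$root
}

# Naive life expectancy: mean remaining days over occupants of (x, j).
oracle_exj <- function(census, x, stage) {
  occ <- vapply(census$daylists, function(dl) dl[x + 1] == stage, logical(1))
  if (!any(occ)) return(NA_real_)
  mean(census$death_age[occ] - x)
}

# Naive reproductive value: explicit double sum over future ages and stages
# with conditional occupancy counts and the global fecundity schedule.
oracle_vxj <- function(census, x, stage, r) {
  sel <- which(vapply(census$daylists, function(dl) dl[x + 1] == stage,
                      logical(1)))
  if (!length(sel)) return(NA_real_)
  x_max <- length(census$l_x) - 1
  adult_fem <- grep("_female$", census$sched_stages, value = TRUE)
  total <- 0
  for (i in x:x_max) {
    for (y in census$sched_stages) {
      cnt <- sum(vapply(census$daylists[sel], function(dl) dl[i + 1] == y,
                        logical(1)))
      f_iy <- if (y == adult_fem) census$f_fem[i + 1] else 0
      total <- total + exp(-r * (i + 1)) * cnt * f_iy
    }
  }
  exp(r * (x + 1)) / length(sel) * total
}

# Small non-reproducing-free config for bootstrap null simulations: modest
# lifespan and fecundity so that type-I / coverage loops stay fast.
null_config <- function(n = 40L, seed = NULL) {
  imm <- c("egg", "L1", "L2", "L3", "L4", "prepupa", "pupa")
  synthetic_config(
    treatment = "null", n = n,
    stage_means = stats::setNames(c(2, 1, 1, 1, 2, 1, 2), imm),
    stage_sds = stats::setNames(c(0.4, 0, 0, 0, 0.4, 0, 0.4), imm),
    stage_survival = stats::setNames(c(0.95, rep(1, 6)), imm),
    female_prob = 0.5, apop_mean = 2, apop_sd = 0.7,
    oviposition_days_target = 8, fecundity_total = 100, fecundity_sd = 30,
    peak_height = 12, peak_age = 16,
    longevity_female_mean = 25, longevity_female_sd = 5,
    longevity_male_mean = 25, longevity_male_sd = 5, seed = seed)
}
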