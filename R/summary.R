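# Cohort-level developmental and reproductive statistics: the classic
# life-table summary rows (stage durations, pre-adult survival, sex ratio,
# APOP, TPOP, oviposition days, fecundity, longevities).

mean_se_n <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  list(mean = if (n) mean(v) else NA_real_,
       se = if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
       n = n)
}

#' Per-stage duration table
#'
#' Mean, plain descriptive SE (`sd/sqrt(n)`) and `n` of the days spent in
#' each immature stage, over the individuals that *completed* the stage
#' (died in a later stage); individuals dying within a stage contribute their
#' partial days to survival schedules but not to duration means. A composite
#' `larva_adult` row gives, per individual reaching adulthood, the sum of all
#' post-egg immature durations (first instar through pupa).
#'
#' @param x A `"cohort"` object.
#' @return Data.frame with columns `stage`, `mean`, `se`, `n`.
#' @export
stage_duration_table <- function(x) {
  validate_cohort(x)
  ind <- active_individuals(x)
  stages <- x$stages
  adult <- stages[length(stages)]
  death_idx <- match(ind$death_stage, stages)
  rows <- lapply(seq_len(length(stages) - 1L), function(j) {
    completed <- death_idx > j
    s <- mean_se_n(ind[[stages[j]]][completed])
    data.frame(stage = stages[j], mean = s$mean, se = s$se, n = s$n,
               stringsAsFactors = FALSE)
  })
  adults <- ind$death_stage == adult
  post_egg <- setdiff(stages, c(stages[1], adult))
  la <- rowSums(as.matrix(ind[adults, post_egg, drop = FALSE]))
  s <- mean_se_n(la)
  rows <- c(rows, list(data.frame(stage = "larva_adult", mean = s$mean,
                                  se = s$se, n = s$n, stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Summarize a cohort's life-history statistics
#'
#' Computes the full set of cohort-level statistics reported for a daily
#' census rearing study:
#' \describe{
#'   \item{stage durations}{via [stage_duration_table()]}
#'   \item{immature duration by sex}{egg-to-adult-emergence days of the
#'     individuals reaching adulthood}
#'   \item{preadult_survival}{fraction of the cohort reaching adulthood}
#'   \item{sex_ratio}{`N_f / (N_f + N_m)` among adults}
#'   \item{apop}{adult pre-oviposition period: days from adult emergence to
#'     first egg, per female that laid}
#'   \item{tpop}{total pre-oviposition period: age at first egg (days since
#'     oviposition). Per female, `tpop = immature duration + apop` exactly.}
#'   \item{oviposition_days}{number of census days with >= 1 egg, per laying
#'     female (not the first-to-last calendar span)}
#'   \item{fecundity}{mean lifetime eggs per adult female (`F`); satisfies
#'     `R0 = F * N_f / N`}
#'   \item{longevity}{both conventions, labelled explicitly: `*_adult` is
#'     days from adult emergence to death, `*_total` is egg-to-death;
#'     `longevity_total` averages egg-to-death over all `N` individuals and
#'     equals `e_{0,egg}` from [life_expectancy()]}
#' }
#' Statistics whose defining set is empty (e.g. APOP on a cohort where no
#' female laid) are reported as `NA` with `n = 0`, never as zero.
#'
#' @param x A `"cohort"` object.
#' @return An object of class `"lifetable_summary"`; use
#'   [as.data.frame.lifetable_summary()] for the flat CSV-ready form.
#' @export
cohort_summary <- function(x) {
  validate_cohort(x)
  ind <- active_individuals(x)
  fec <- active_fecundity(x)
  stages <- x$stages
  adult <- stages[length(stages)]
  N <- nrow(ind)
  adults <- ind$death_stage == adult
  is_f <- adults & ind$sex == "female"
  is_m <- adults & ind$sex == "male"
  emergence <- immature_duration(x, ind)
  fec <- fec[fec$eggs > 0, , drop = FALSE]
  first_egg <- rep(NA_real_, N)
  total_eggs <- rep(0, N)
  ovi_days <- rep(0, N)
  if (nrow(fec)) {
    agg_min <- tapply(fec$age_day, fec$id, min)
    agg_sum <- tapply(fec$eggs, fec$id, sum)
    agg_n <- tapply(fec$eggs, fec$id, length)
    m <- match(names(agg_min), ind$id)
    first_egg[m] <- as.numeric(agg_min)
    total_eggs[m] <- as.numeric(agg_sum)
    ovi_days[m] <- as.numeric(agg_n)
  }
  laid <- is_f & !is.na(first_egg)
  n_f <- sum(is_f); n_m <- sum(is_m)
  out <- list(
    treatment = x$treatment,
    N = N,
    n_adults = sum(adults),
    n_females = n_f,
    n_males = n_m,
    stage_durations = stage_duration_table(x),
    immature_female = mean_se_n(emergence[is_f]),
    immature_male = mean_se_n(emergence[is_m]),
    preadult_survival = list(mean = sum(adults) / N, se = NA_real_, n = N),
    sex_ratio = list(
      mean = if (n_f + n_m > 0) n_f / (n_f + n_m) else NA_real_,
      se = NA_real_, n = n_f + n_m),
    apop = mean_se_n(first_egg[laid] - emergence[laid]),
    tpop = mean_se_n(first_egg[laid]),
    oviposition_days = mean_se_n(ovi_days[laid]),
    fecundity = mean_se_n(total_eggs[is_f]),
    longevity_female_adult = mean_se_n(ind$death_age[is_f] - emergence[is_f]),
    longevity_male_adult = mean_se_n(ind$death_age[is_m] - emergence[is_m]),
    longevity_female_total = mean_se_n(ind$death_age[is_f]),
    longevity_male_total = mean_se_n(ind$death_age[is_m]),
    longevity_total = mean_se_n(ind$death_age)
  )
  class(out) <- "lifetable_summary"
  out
}

summary_definitions <- c(
  immature_female = "egg-to-adult-emergence days, females",
  immature_male = "egg-to-adult-emergence days, males",
  preadult_survival = "fraction of cohort reaching adulthood",
  sex_ratio = "N_f / (N_f + N_m) among adults",
  apop = "adult emergence to first egg, days, laying females",
  tpop = "age at first egg, days since oviposition, laying females",
  oviposition_days = "census days with >= 1 egg, per laying female",
  fecundity = "lifetime eggs per adult female (F)",
  longevity_female_adult = "adult emergence to death, days, females",
  longevity_male_adult = "adult emergence to death, days, males",
  longevity_female_total = "egg to death, days, females",
  longevity_male_total = "egg to death, days, males",
  longevity_total = "egg to death, days, all individuals"
)

#' Flatten a lifetable summary to one row per statistic
#'
#' @param x A `"lifetable_summary"`.
#' @param ... Unused.
#' @return Data.frame with columns `statistic`, `mean`, `se`, `n`,
#'   `definition` (stage-duration rows included).
#' @export
as.data.frame.lifetable_summary <- function(x, ...) {
  sd_tab <- x$stage_durations
  stage_rows <- data.frame(
    statistic = paste0("duration_", sd_tab$stage),
    mean = sd_tab$mean, se = sd_tab$se, n = sd_tab$n,
    definition = paste0("days in stage ", sd_tab$stage,
                        " (completers only)"),
    stringsAsFactors = FALSE)
  scalar <- names(summary_definitions)
  other <- do.call(rbind, lapply(scalar, function(nm) {
    s <- x[[nm]]
    data.frame(statistic = nm, mean = s$mean, se = s$se, n = s$n,
               definition = unname(summary_definitions[nm]),
               stringsAsFactors = FALSE)
  }))
  rbind(stage_rows, other)
}

#' @export
print.lifetable_summary <- function(x, ...) {
  cat(sprintf("<lifetable_summary> '%s': N = %d, adults = %d (%d f / %d m)\n",
              x$treatment, x$N, x$n_adults, x$n_females, x$n_males))
  df <- as.data.frame(x)
  df$mean <- round(df$mean, 3)
  df$se <- round(df$se, 3)
  print(df[, c("statistic", "mean", "se", "n")], row.names = FALSE)
  invisible(x)
}
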