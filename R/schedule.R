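# Occupancy machinery shared by the schedule builder, the life-expectancy /
# reproductive-value computations and the bootstrap fast path.
#
# Conventions: age 0 is the day of oviposition; the daily census maps to unit
# age classes, so an individual with death_age D is alive on census days
# 0 .. D-1. A stage entered with cumulative start c and duration d is occupied
# on days c .. c+d-1. The adult (last) stage is split by sex into
# "<adult>_female" and "<adult>_male" columns.

# Integer matrix (individuals x ages 0..x_max) of schedule-stage indices,
# 0 = dead. Schedule stages = immature ontology stages + adult split by sex.
occupancy_matrix <- function(ind, stages) {
  n <- nrow(ind)
  adult <- stages[length(stages)]
  sched_stages <- c(stages[-length(stages)],
                    paste0(adult, "_female"), paste0(adult, "_male"))
  x_max <- max(ind$death_age) - 1L
  occ <- matrix(0L, nrow = n, ncol = x_max + 1L,
                dimnames = list(ind$id, NULL))
  dur <- as.matrix(ind[, stages, drop = FALSE])
  storage.mode(dur) <- "double"
  n_imm <- length(stages) - 1L
  for (i in seq_len(n)) {
    d <- dur[i, ]
    entered <- which(!is.na(d))
    stop_at <- cumsum(d[entered])
    start_at <- c(0, stop_at[-length(stop_at)])
    for (k in seq_along(entered)) {
      j <- entered[k]
      idx <- if (j <= n_imm) j else {
        if (ind$sex[i] == "female") n_imm + 1L else n_imm + 2L
      }
      occ[i, seq.int(start_at[k] + 1L, stop_at[k])] <- idx
    }
  }
  structure(occ, sched_stages = sched_stages)
}

# Individuals x ages matrix of daily egg counts, aligned with occupancy.
eggs_matrix <- function(ind, fec, n_ages) {
  E <- matrix(0, nrow = nrow(ind), ncol = n_ages,
              dimnames = list(ind$id, NULL))
  if (nrow(fec)) {
    i <- match(fec$id, ind$id)
    keep <- fec$age_day <= n_ages - 1L
    E[cbind(i[keep], fec$age_day[keep] + 1L)] <- fec$eggs[keep]
  }
  E
}

#' Build the age-stage schedule of a cohort
#'
#' Tabulates, from the per-individual daily trajectories, the age-stage
#' specific survival rate `s_xj` (probability that a freshly oviposited egg is
#' alive and in stage `j` at age `x`; an empirical multiple of `1/N`), the
#' stage-specific fecundity `f_xj` (mean eggs laid at age `x` per individual
#' alive in stage `j`; nonzero only in the adult-female stage), and the derived
#' age-specific survival `l_x = sum_j s_xj` and fecundity
#' `m_x = sum_j s_xj f_xj / l_x` (0 where `l_x = 0`).
#'
#' The adult stage is split into female and male columns, as the two-sex
#' method requires; individuals dying before adulthood contribute their
#' partial days in the death stage to `s_xj`.
#'
#' @param x A `"cohort"` object with at least one non-excluded individual.
#' @return An object of class `"age_stage_schedule"`: list with `ages`
#'   (integer vector starting at 0), `stages` (schedule stage names), `s_xj`
#'   and `f_xj` (ages x stages matrices), `l_x`, `m_x`, `N`, `treatment`, and
#'   the per-individual trajectory matrices used by [life_expectancy()] and
#'   [reproductive_value()].
#' @export
#' @examples
#' coh <- fixture_cohort("t_ogmophallos")
#' sched <- build_schedule(coh)
#' max(sched$s_xj[, "adult_female"]) # peak adult-female survival curve
build_schedule <- function(x) {
  validate_cohort(x)
  ind <- active_individuals(x)
  if (!nrow(ind)) {
    stop_agestage("validation", "cohort has no non-excluded individuals")
  }
  fec <- active_fecundity(x)
  occ <- occupancy_matrix(ind, x$stages)
  sched_stages <- attr(occ, "sched_stages")
  n_ages <- ncol(occ)
  N <- nrow(ind)
  counts <- vapply(seq_along(sched_stages),
                   function(j) colSums(occ == j), numeric(n_ages))
  dimnames(counts) <- list(NULL, sched_stages)
  s_xj <- counts / N
  E <- eggs_matrix(ind, fec, n_ages)
  eggs_by_age <- colSums(E)
  fem_col <- length(sched_stages) - 1L
  fem_alive <- counts[, fem_col]
  f_xj <- matrix(0, nrow = n_ages, ncol = length(sched_stages),
                 dimnames = dimnames(counts))
  f_xj[, fem_col] <- ifelse(fem_alive > 0, eggs_by_age / fem_alive, 0)
  l_x <- rowSums(s_xj)
  m_x <- ifelse(l_x > 0, rowSums(s_xj * f_xj) / l_x, 0)
  structure(
    list(ages = 0:(n_ages - 1L), stages = sched_stages, s_xj = s_xj,
         f_xj = f_xj, l_x = l_x, m_x = m_x, N = N, treatment = x$treatment,
         occupancy = occ, eggs = E, death_age = ind$death_age),
    class = "age_stage_schedule"
  )
}

#' @export
print.age_stage_schedule <- function(x, ...) {
  cat(sprintf("<age_stage_schedule> '%s': N = %d, ages 0..%d\n",
              x$treatment, x$N, max(x$ages)))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = ", ")))
  R0 <- sum(x$l_x * x$m_x)
  cat(sprintf("  R0 = sum l_x m_x = %.4f\n", R0))
  invisible(x)
}

#' Tidy long-format view of schedule curves
#'
#' @param x An `"age_stage_schedule"`.
#' @param ... Unused.
#' @return A data.frame with columns `age`, `stage` (`NA` for the age-only
#'   curves `l_x` and `m_x`), `variable` (`"s_xj"`, `"f_xj"`, `"l_x"`,
#'   `"m_x"`) and `value` — the data behind survival/fecundity curve figures.
#' @export
as.data.frame.age_stage_schedule <- function(x, ...) {
  n_ages <- length(x$ages)
  long <- function(mat, name) {
    data.frame(age = rep(x$ages, times = ncol(mat)),
               stage = rep(colnames(mat), each = n_ages),
               variable = name, value = as.vector(mat),
               stringsAsFactors = FALSE)
  }
  rbind(
    long(x$s_xj, "s_xj"),
    long(x$f_xj, "f_xj"),
    data.frame(age = x$ages, stage = NA_character_, variable = "l_x",
               value = x$l_x, stringsAsFactors = FALSE),
    data.frame(age = x$ages, stage = NA_character_, variable = "m_x",
               value = x$m_x, stringsAsFactors = FALSE)
  )
}

#' Plot the age-stage survival curves
#'
#' Base-graphics convenience plot of `s_xj` against age, one line per stage
#' (the classic overlapping survival-curve panel), plus `l_x` in black.
#'
#' @param x An `"age_stage_schedule"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.age_stage_schedule <- function(x, ...) {
  graphics::matplot(x$ages, cbind(x$s_xj, l_x = x$l_x), type = "l",
                    lty = c(rep(1, ncol(x$s_xj)), 2),
                    col = c(seq_len(ncol(x$s_xj)), 1),
                    xlab = "age (days)", ylab = expression(s[xj]), ...)
  graphics::legend("topright", legend = c(colnames(x$s_xj), "l_x"),
                   lty = c(rep(1, ncol(x$s_xj)), 2),
                   col = c(seq_len(ncol(x$s_xj)), 1), cex = 0.7, bty = "n")
  invisible(x)
}
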