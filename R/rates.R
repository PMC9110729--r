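# Demographic parameters of the two-sex life table: R0, r, lambda, T, e_xj,
# v_xj. All age indexing starts at 0 (oviposition day) and the Euler-Lotka
# exponent uses (x + 1):  sum_x exp(-r (x+1)) l_x m_x = 1.
# The off-by-one matters: with typical schedules it moves r in the third
# decimal, so the convention is asserted by tests.

#' Net reproductive rate
#'
#' `R0 = sum_x l_x m_x`: the expected lifetime egg output per individual of
#' the initial cohort (both sexes and pre-adult deaths included in the
#' denominator). On every empirical schedule this equals `F * N_f / N`, the
#' mean eggs per female times the proportion of females — a cross-check the
#' test suite enforces.
#'
#' @param sched An `"age_stage_schedule"` from [build_schedule()].
#' @return Non-negative scalar, eggs per initial individual.
#' @export
net_reproductive_rate <- function(sched) {
  stopifnot(inherits(sched, "age_stage_schedule"))
  sum(sched$l_x * sched$m_x)
}

# Euler-Lotka solver on the l_x m_x vector (age 0 first). Bracketed bisection
# on [-5, 5] followed by Newton polishing with the analytic derivative;
# deterministic. Residual tolerance applies to |sum exp(-r(x+1)) lxmx - 1|.
solve_euler_lotka <- function(lxmx, tol = 1e-12, max_iter = 200L) {
  R0 <- sum(lxmx)
  if (!is.finite(R0) || R0 <= 0) {
    stop_agestage("undefined_rate",
                  "intrinsic rate undefined: net reproductive rate is 0 ",
                  "(no reproduction in this cohort)")
  }
  pos <- which(lxmx > 0) # drop zero terms: exp() may overflow at bracket ends
  x1 <- pos # = x + 1 for x = 0, 1, ... (ages count from 0)
  lxmx <- lxmx[pos]
  f <- function(r) sum(exp(-r * x1) * lxmx) - 1
  lo <- -5; hi <- 5
  flo <- f(lo); fhi <- f(hi)
  if (!(flo > 0 && fhi < 0)) {
    stop_agestage("undefined_rate",
                  "Euler-Lotka root not bracketed in [-5, 5]")
  }
  for (i in seq_len(100L)) { # bisection: interval below 1e-8 after ~60 steps
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  r <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    res <- f(r)
    if (abs(res) < tol) break
    fp <- -sum(x1 * exp(-r * x1) * lxmx)
    r_new <- r - res / fp
    if (!is.finite(r_new)) break
    r <- r_new
  }
  if (abs(f(r)) >= tol) {
    warning("Euler-Lotka residual ", format(abs(f(r))),
            " did not reach tolerance ", format(tol))
  }
  r
}

#' Intrinsic rate of increase
#'
#' Solves the Euler-Lotka equation `sum_x exp(-r (x+1)) l_x m_x = 1` (age
#' indexed from 0) for the per-day intrinsic rate of increase `r`, by
#' bracketed bisection on `[-5, 5]` followed by Newton polishing. `r > 0`
#' exactly when `R0 > 1`.
#'
#' @param sched An `"age_stage_schedule"`.
#' @param tol Residual tolerance for the Euler-Lotka equation.
#' @param max_iter Maximum Newton iterations after bisection.
#' @return `r` in day^-1. Throws an error of class
#'   `"agestage_undefined_rate_error"` when `R0 = 0` (e.g. a diet on which no
#'   individual reproduced), so callers can report the parameter as undefined
#'   rather than crash.
#' @export
intrinsic_rate <- function(sched, tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(sched, "age_stage_schedule"))
  solve_euler_lotka(sched$l_x * sched$m_x, tol = tol, max_iter = max_iter)
}

#' Finite rate of increase
#'
#' `lambda = exp(r)`, the per-day multiplication factor of the population.
#'
#' @param r Intrinsic rate of increase (day^-1).
#' @return `lambda` in day^-1.
#' @export
finite_rate <- function(r) {
  stopifnot(is.finite(r))
  exp(r)
}

#' Mean generation time
#'
#' `T = ln(R0) / r`: the time a population needs to grow `R0`-fold at the
#' stable rate `r`.
#'
#' @param R0 Net reproductive rate (> 0).
#' @param r Intrinsic rate of increase.
#' @return `T` in days; `NA_real_` (with a warning) when undefined
#'   (`R0 <= 0`, or `r = 0` with `R0 = 1`).
#' @export
mean_generation_time <- function(R0, r) {
  if (!is.finite(R0) || R0 <= 0 || !is.finite(r) || r == 0) {
    warning("mean generation time undefined for R0 = ", R0, ", r = ", r)
    return(NA_real_)
  }
  log(R0) / r
}

#' Age-stage life expectancy
#'
#' `e_xj`: the expected remaining lifespan (days) of an individual that is
#' alive in stage `j` at age `x`, computed from the empirical per-individual
#' trajectories — the mean of `death_age - x` over the individuals observed
#' in `(x, j)`. At age 0 in the first stage this equals the cohort mean
#' lifespan, deaths included. Cells never occupied are `NA`.
#'
#' @param sched An `"age_stage_schedule"`.
#' @return Ages x stages matrix of expectancies in days.
#' @export
life_expectancy <- function(sched) {
  stopifnot(inherits(sched, "age_stage_schedule"))
  occ <- sched$occupancy
  death <- sched$death_age
  n_ages <- ncol(occ)
  n_st <- length(sched$stages)
  e <- matrix(NA_real_, nrow = n_ages, ncol = n_st,
              dimnames = list(NULL, sched$stages))
  for (x in seq_len(n_ages)) { # x is age + 1
    here <- occ[, x]
    for (j in seq_len(n_st)) {
      sel <- here == j
      if (any(sel)) e[x, j] <- mean(death[sel] - (x - 1L))
    }
  }
  e
}

#' Age-stage reproductive value
#'
#' `v_xj`: the expected contribution of an individual alive in stage `j` at
#' age `x` to future population growth,
#' `v_xj = e^{r(x+1)} / s_xj * sum_{i >= x} e^{-r(i+1)} sum_y s'_iy f_iy`,
#' where `s'_iy` is the occupancy of ages/stages conditional on being in
#' `(x, j)`, taken from the empirical trajectories, and `f_iy` is the cohort
#' fecundity schedule. At age 0 in the first stage `v` equals `lambda`
#' exactly — a consequence of the Euler-Lotka equation that the test suite
#' asserts on every cohort with `R0 > 0`.
#'
#' @param sched An `"age_stage_schedule"` with `R0 > 0`.
#' @param r Intrinsic rate; computed from `sched` when omitted.
#' @return Ages x stages matrix; `NA` for cells never occupied.
#' @export
reproductive_value <- function(sched, r = NULL) {
  stopifnot(inherits(sched, "age_stage_schedule"))
  if (is.null(r)) r <- intrinsic_rate(sched)
  occ <- sched$occupancy
  n_ages <- ncol(occ)
  n_st <- length(sched$stages)
  # per-individual discounted fecundity credit c_i(a) = e^{-r(a+1)} f_{a, occ}
  f_flat <- cbind(0, sched$f_xj) # column 1 = dead (credit 0)
  credit <- matrix(f_flat[cbind(rep(seq_len(n_ages), each = nrow(occ)),
                                as.vector(occ) + 1L)],
                   nrow = nrow(occ))
  credit <- sweep(credit, 2L, exp(-r * seq_len(n_ages)), `*`)
  # tail sums T_i(x) = sum_{a >= x} c_i(a)
  tails <- t(apply(credit, 1L, function(z) rev(cumsum(rev(z)))))
  v <- matrix(NA_real_, nrow = n_ages, ncol = n_st,
              dimnames = list(NULL, sched$stages))
  for (x in seq_len(n_ages)) {
    here <- occ[, x]
    for (j in seq_len(n_st)) {
      sel <- here == j
      if (any(sel)) v[x, j] <- exp(r * x) * mean(tails[sel, x])
    }
  }
  v
}

#' All scalar demographic parameters of a cohort
#'
#' Convenience wrapper computing `R0`, `r`, `lambda` and `T` together, with
#' the zero-reproduction case reported as `NA` (not an error): on a diet
#' where no individual reproduces, `R0 = 0` and `r`, `lambda`, `T` are
#' undefined.
#'
#' @param sched An `"age_stage_schedule"`.
#' @return Named list with `R0`, `r`, `lambda`, `T` (days).
#' @export
demographic_parameters <- function(sched) {
  R0 <- net_reproductive_rate(sched)
  r <- tryCatch(intrinsic_rate(sched),
                agestage_undefined_rate_error = function(e) NA_real_)
  lambda <- if (is.finite(r)) finite_rate(r) else NA_real_
  Tg <- if (is.finite(r) && r != 0 && R0 > 0) log(R0) / r else NA_real_
  list(R0 = R0, r = r, lambda = lambda, T = Tg)
}
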