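# Bootstrap inference. The resampling unit is the individual: each replicate
# draws N individuals with replacement from the cohort and recomputes the
# statistic from scratch (life-table parameters included, via the
# per-individual trajectory matrices precomputed once per cohort).

# Precompute everything a statistic needs, so a replicate is a cheap
# row-subset. All vectors follow the order of active_individuals(x).
boot_data <- function(x) {
  validate_cohort(x)
  ind <- active_individuals(x)
  if (!nrow(ind)) {
    stop_agestage("validation", "cohort has no non-excluded individuals")
  }
  fec <- active_fecundity(x)
  stages <- x$stages
  adult <- stages[length(stages)]
  occ <- occupancy_matrix(ind, stages)
  E <- eggs_matrix(ind, fec, ncol(occ))
  adults <- ind$death_stage == adult
  emergence <- immature_duration(x, ind)
  fec <- fec[fec$eggs > 0, , drop = FALSE]
  n <- nrow(ind)
  first_egg <- rep(NA_real_, n)
  ovi <- rep(0, n)
  if (nrow(fec)) {
    m <- match(names(tapply(fec$age_day, fec$id, min)), ind$id)
    first_egg[m] <- as.numeric(tapply(fec$age_day, fec$id, min))
    ovi[m] <- as.numeric(tapply(fec$eggs, fec$id, length))
  }
  death_idx <- match(ind$death_stage, stages)
  dur <- as.matrix(ind[, stages[-length(stages)], drop = FALSE])
  storage.mode(dur) <- "double"
  list(n = n,
       total_eggs = rowSums(E), E = E,
       is_adult = adults,
       is_female = adults & ind$sex == "female",
       is_male = adults & ind$sex == "male",
       emergence = emergence, first_egg = first_egg, ovi = ovi,
       death_age = ind$death_age, death_idx = death_idx,
       dur = dur, n_imm = length(stages) - 1L)
}

boot_r <- function(bd, idx) {
  lxmx <- colSums(bd$E[idx, , drop = FALSE]) / length(idx)
  if (sum(lxmx) <= 0) return(NA_real_)
  solve_euler_lotka(lxmx)
}

stat_registry <- function() {
  safe_mean <- function(v) if (length(v)) mean(v) else NA_real_
  base <- list(
    fecundity = function(bd, idx) {
      f <- bd$is_female[idx]
      if (!any(f)) return(NA_real_)
      sum(bd$total_eggs[idx][f]) / sum(f)
    },
    R0 = function(bd, idx) sum(bd$total_eggs[idx]) / length(idx),
    r = boot_r,
    lambda = function(bd, idx) {
      r <- boot_r(bd, idx)
      if (is.na(r)) NA_real_ else exp(r)
    },
    T = function(bd, idx) {
      R0 <- sum(bd$total_eggs[idx]) / length(idx)
      if (R0 <= 0) return(NA_real_)
      r <- boot_r(bd, idx)
      if (is.na(r) || r == 0) NA_real_ else log(R0) / r
    },
    apop = function(bd, idx) {
      sel <- bd$is_female[idx] & !is.na(bd$first_egg[idx])
      safe_mean((bd$first_egg[idx] - bd$emergence[idx])[sel])
    },
    tpop = function(bd, idx) {
      sel <- bd$is_female[idx] & !is.na(bd$first_egg[idx])
      safe_mean(bd$first_egg[idx][sel])
    },
    oviposition_days = function(bd, idx) {
      sel <- bd$is_female[idx] & !is.na(bd$first_egg[idx])
      safe_mean(bd$ovi[idx][sel])
    },
    sex_ratio = function(bd, idx) {
      nf <- sum(bd$is_female[idx]); nm <- sum(bd$is_male[idx])
      if (nf + nm == 0) NA_real_ else nf / (nf + nm)
    },
    preadult_survival = function(bd, idx) sum(bd$is_adult[idx]) / length(idx),
    immature_female = function(bd, idx)
      safe_mean(bd$emergence[idx][bd$is_female[idx]]),
    immature_male = function(bd, idx)
      safe_mean(bd$emergence[idx][bd$is_male[idx]]),
    longevity_female_adult = function(bd, idx) {
      sel <- bd$is_female[idx]
      safe_mean((bd$death_age[idx] - bd$emergence[idx])[sel])
    },
    longevity_male_adult = function(bd, idx) {
      sel <- bd$is_male[idx]
      safe_mean((bd$death_age[idx] - bd$emergence[idx])[sel])
    },
    longevity_total = function(bd, idx) mean(bd$death_age[idx])
  )
  base
}

# Duration statistics are generated per stage name: "duration_<stage>".
stat_function <- function(statistic) {
  reg <- stat_registry()
  if (statistic %in% names(reg)) return(reg[[statistic]])
  if (startsWith(statistic, "duration_")) {
    stage <- sub("^duration_", "", statistic)
    return(function(bd, idx) {
      j <- match(stage, colnames(bd$dur))
      if (is.na(j)) stop_agestage("validation", "unknown stage: ", stage)
      sel <- bd$death_idx[idx] > j
      if (!any(sel)) return(NA_real_)
      mean(bd$dur[idx, j][sel])
    })
  }
  stop_agestage("validation", "unknown statistic: ", statistic)
}

#' Names of the bootstrappable life-table statistics
#'
#' @param x Optional `"cohort"`; when given, per-stage duration statistics
#'   (`duration_<stage>`) for its ontology are appended.
#' @return Character vector of statistic names accepted by
#'   [bootstrap_lifetable()] and [paired_bootstrap_test()].
#' @export
lifetable_statistics <- function(x = NULL) {
  nm <- names(stat_registry())
  if (!is.null(x)) {
    nm <- c(nm, paste0("duration_", x$stages[-length(x$stages)]))
  }
  nm
}

# Core engine: replicate values for one cohort. Returns numeric vector of
# length B (NA = degenerate replicate).
boot_values <- function(bd, fun, B, seed) {
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(bd$n, bd$n * B, replace = TRUE), nrow = bd$n)
  vapply(seq_len(B), function(b) fun(bd, idx[, b]), numeric(1))
}

#' Bootstrap a life-table statistic
#'
#' Resamples the cohort's individuals with replacement (`N` draws per
#' replicate), recomputes the statistic on each replicate — life-table
#' parameters (`r`, `lambda`, `R0`, `T`) are re-derived from the resampled
#' schedule, not approximated — and reports the bootstrap SE and the 95%
#' percentile confidence interval. Replicates on which the statistic is
#' undefined (e.g. an all-male resample for `R0`-derived rates) are skipped
#' and counted; a warning is issued when they exceed 1% of `B`.
#'
#' @param x A `"cohort"` object.
#' @param statistic Statistic name; see [lifetable_statistics()].
#' @param B Number of bootstrap resamples. The study-design default is
#'   100,000; use far fewer for interactive work.
#' @param seed Integer seed making the resampling reproducible.
#' @param conf Confidence level of the percentile interval.
#' @return An object of class `"boot_result"` with fields `statistic`, `B`,
#'   `seed`, `point` (full-cohort value), `se`, `ci` (percentile), `values`
#'   (all replicate values) and `degenerate` (count of undefined replicates).
#' @export
bootstrap_lifetable <- function(x, statistic, B = 100000L, seed = NULL,
                                conf = 0.95) {
  stopifnot(B >= 1)
  bd <- boot_data(x)
  fun <- stat_function(statistic)
  point <- fun(bd, seq_len(bd$n))
  if (is.na(point)) {
    stop_agestage("validation", "statistic '", statistic,
                  "' is undefined on the full cohort")
  }
  vals <- boot_values(bd, fun, B, seed)
  ok <- vals[!is.na(vals)]
  degenerate <- sum(is.na(vals))
  if (degenerate > 0.01 * B) {
    warning(sprintf("%d of %d replicates (%.1f%%) were degenerate for '%s'",
                    degenerate, B, 100 * degenerate / B, statistic))
  }
  alpha <- (1 - conf) / 2
  structure(
    list(statistic = statistic, treatment = x$treatment, B = B, seed = seed,
         point = point,
         se = if (length(ok) > 1) stats::sd(ok) else 0,
         ci = stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE),
         conf = conf, values = vals, degenerate = degenerate),
    class = "boot_result"
  )
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf(
    "<boot_result> %s ('%s'): %.4f, SE %.4f, %g%% CI [%.4f, %.4f]\n",
    x$statistic, x$treatment, x$point, x$se, 100 * x$conf,
    x$ci[1], x$ci[2]))
  cat(sprintf("  B = %d, degenerate = %d, seed = %s\n",
              x$B, x$degenerate, format(x$seed)))
  invisible(x)
}

#' Paired bootstrap test between two cohorts
#'
#' Per replicate, each cohort is resampled independently (its own `N` draws
#' with replacement) and the difference of the statistic recorded; the two
#' treatments differ significantly when the 95% percentile confidence
#' interval of the differences excludes zero. Replicates where either arm is
#' degenerate are dropped and counted.
#'
#' @param a,b `"cohort"` objects.
#' @param statistic Statistic name; see [lifetable_statistics()].
#' @param B Number of replicates (study-design default 100,000).
#' @param seed Integer seed; arm substreams are derived as `seed` and
#'   `seed + 1` unless `arm_seeds` overrides them.
#' @param arm_seeds Optional length-2 integer vector of per-arm seeds (passing
#'   the same seed twice reproduces the identical resampling stream in both
#'   arms, so a cohort compared with itself gives an all-zero difference).
#' @param conf Confidence level.
#' @return Object of class `"paired_boot_result"` with the point difference
#'   (`a - b`), percentile CI of the bootstrap differences, significance flag
#'   and degenerate count.
#' @export
paired_bootstrap_test <- function(a, b, statistic, B = 100000L, seed = NULL,
                                  arm_seeds = NULL, conf = 0.95) {
  stopifnot(B >= 1)
  if (is.null(arm_seeds)) {
    arm_seeds <- if (is.null(seed)) c(NA, NA) else c(seed, seed + 1L)
  }
  fun <- stat_function(statistic)
  bda <- boot_data(a); bdb <- boot_data(b)
  pa <- fun(bda, seq_len(bda$n)); pb <- fun(bdb, seq_len(bdb$n))
  if (is.na(pa) || is.na(pb)) {
    stop_agestage("validation", "statistic '", statistic,
                  "' is undefined on one of the cohorts")
  }
  va <- boot_values(bda, fun, B, if (is.na(arm_seeds[1])) NULL else arm_seeds[1])
  vb <- boot_values(bdb, fun, B, if (is.na(arm_seeds[2])) NULL else arm_seeds[2])
  d <- va - vb
  ok <- d[!is.na(d)]
  degenerate <- sum(is.na(d))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(statistic = statistic, treatments = c(a$treatment, b$treatment),
         B = B, seed = seed, arm_seeds = arm_seeds,
         estimate = pa - pb, mean_difference = mean(ok), ci = ci, conf = conf,
         significant = ci[1] > 0 || ci[2] < 0, degenerate = degenerate),
    class = "paired_boot_result"
  )
}

#' @export
print.paired_boot_result <- function(x, ...) {
  cat(sprintf(
    "<paired_boot_result> %s: '%s' - '%s' = %.4f, %g%% CI [%.4f, %.4f] -> %s\n",
    x$statistic, x$treatments[1], x$treatments[2], x$estimate,
    100 * x$conf, x$ci[1], x$ci[2],
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# Compact letter display from a pairwise non-significance relation.
# Treatments must be ordered (by descending estimate); groups are the maximal
# subsets in which no pair differs; letters assigned in order of the group's
# best-ranked member. Brute-force over subsets (k is small).
cld_letters <- function(ns_matrix) {
  k <- nrow(ns_matrix)
  stopifnot(k >= 1, k <= 12)
  diag(ns_matrix) <- TRUE
  subsets <- lapply(seq_len(2^k - 1), function(code) which(bitwAnd(
    code, 2^(seq_len(k) - 1)) > 0))
  compat <- vapply(subsets, function(s) all(ns_matrix[s, s]), logical(1))
  cliques <- subsets[compat]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(other)
      length(other) > length(cliques[[i]]) && all(cliques[[i]] %in% other),
      logical(1)))
  }, logical(1))]
  ord <- order(vapply(maximal, min, numeric(1)),
               vapply(maximal, function(s) -length(s), numeric(1)))
  maximal <- maximal[ord]
  letters_out <- character(k)
  for (g in seq_along(maximal)) {
    members <- maximal[[g]]
    letters_out[members] <- paste0(letters_out[members], letters[g])
  }
  letters_out
}

#' Compare several treatments with paired bootstrap tests
#'
#' Runs every pairwise [paired_bootstrap_test()] on a named list of cohorts
#' and derives a compact letter display: treatments sharing a letter do not
#' differ at the chosen level. Each treatment gets its own resampling
#' substream (`seed + position`), reused across its pairwise comparisons so
#' the letter display is internally consistent.
#'
#' @param cohorts Named list of two or more `"cohort"` objects.
#' @param statistic Statistic name.
#' @param B Replicates per treatment.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Object of class `"treatment_comparison"`: data.frame `table`
#'   (treatment, estimate, letter, ordered by descending estimate) plus the
#'   pairwise results in `pairs`.
#' @export
compare_treatments <- function(cohorts, statistic, B = 100000L, seed = NULL,
                               conf = 0.95) {
  stopifnot(length(cohorts) >= 2, !is.null(names(cohorts)))
  fun <- stat_function(statistic)
  bds <- lapply(cohorts, boot_data)
  points <- vapply(bds, function(bd) fun(bd, seq_len(bd$n)), numeric(1))
  if (anyNA(points)) {
    stop_agestage("validation", "statistic '", statistic,
                  "' undefined on cohort(s): ",
                  paste(names(points)[is.na(points)], collapse = ", "))
  }
  vals <- lapply(seq_along(bds), function(i) {
    boot_values(bds[[i]], fun, B,
                if (is.null(seed)) NULL else seed + i)
  })
  k <- length(cohorts)
  alpha <- (1 - conf) / 2
  pairs <- list()
  sig <- matrix(FALSE, k, k, dimnames = list(names(cohorts), names(cohorts)))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      d <- vals[[i]] - vals[[j]]
      ok <- d[!is.na(d)]
      ci <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
      s <- ci[1] > 0 || ci[2] < 0
      sig[i, j] <- sig[j, i] <- s
      pairs[[paste(names(cohorts)[i], names(cohorts)[j], sep = " vs ")]] <-
        list(estimate = points[i] - points[j], ci = ci, significant = s,
             degenerate = sum(is.na(d)))
    }
  }
  ord <- order(-points)
  letters_out <- cld_letters(!sig[ord, ord, drop = FALSE])
  tab <- data.frame(treatment = names(cohorts)[ord],
                    estimate = unname(points[ord]),
                    letter = letters_out, stringsAsFactors = FALSE)
  structure(list(statistic = statistic, B = B, seed = seed, conf = conf,
                 table = tab, pairs = pairs, significant = sig),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("<treatment_comparison> %s (B = %d):\n", x$statistic, x$B))
  print(x$table, row.names = FALSE)
  invisible(x)
}
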