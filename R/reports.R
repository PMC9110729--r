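# Report front end: the analyze / compare / simulate entry points behind the
# command-line script in inst/scripts/agestage-cli.R. CSV files are the
# contract; every output is deterministic given (input, B, seed).

resolve_cohort <- function(input, stages = default_stage_ontology()) {
  if (inherits(input, "cohort")) return(input)
  if (is.character(input) && length(input) == 1) {
    if (file.exists(input)) return(read_cohort(input, stages = stages))
    presets <- c("t_urticae", "t_evansi", "t_ogmophallos", "m_persicae")
    if (input %in% presets) {
      return(simulate_cohort(preset_config(input, seed = 0L)))
    }
    stop_agestage("format", "input '", input,
                  "' is neither a file nor a known preset")
  }
  stop_agestage("format", "cannot interpret cohort input")
}

write_df <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Analyze a cohort and write the full set of report files
#'
#' Runs the whole pipeline on one cohort: the life-history summary (the
#' layout of a stage-duration / reproduction table), the demographic
#' parameters `R0`, `r`, `lambda`, `T` with bootstrap SEs and percentile
#' CIs, and the tidy curve files behind the survival / fecundity /
#' life-expectancy / reproductive-value figures. On a zero-reproduction
#' cohort `r`, `lambda`, `T` and the reproductive-value curves are reported
#' as undefined (empty cells), not an error.
#'
#' @param input A `"cohort"`, a path to an individual-CSV file, or a preset
#'   name (simulated with seed 0).
#' @param out_dir Output directory, created if needed.
#' @param B Bootstrap replicates for the parameter SEs.
#' @param seed Integer seed for the bootstrap.
#' @return Invisibly, a named character vector of files written
#'   (`summary.csv`, `parameters.csv`, `curves_schedule.csv`,
#'   `curves_expectancy.csv`, `curves_value.csv`).
#' @export
run_analyze <- function(input, out_dir, B = 2000L, seed = 0L) {
  coh <- resolve_cohort(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_df <- as.data.frame(cohort_summary(coh))
  sched <- build_schedule(coh)
  pars <- demographic_parameters(sched)
  par_rows <- lapply(names(pars), function(nm) {
    if (!is.finite(pars[[nm]]) || (nm != "R0" && is.na(pars$r))) {
      return(data.frame(parameter = nm, estimate = pars[[nm]], se = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, B = B, seed = seed,
                        degenerate = NA_integer_, stringsAsFactors = FALSE))
    }
    br <- bootstrap_lifetable(coh, nm, B = B, seed = seed)
    data.frame(parameter = nm, estimate = br$point, se = br$se,
               ci_lo = br$ci[1], ci_hi = br$ci[2], B = B, seed = seed,
               degenerate = br$degenerate, stringsAsFactors = FALSE)
  })
  params_df <- do.call(rbind, par_rows)
  curves <- as.data.frame(sched)
  e <- life_expectancy(sched)
  exj <- data.frame(age = rep(sched$ages, times = ncol(e)),
                    stage = rep(colnames(e), each = length(sched$ages)),
                    e_xj = as.vector(e), stringsAsFactors = FALSE)
  if (is.finite(pars$r)) {
    v <- reproductive_value(sched, pars$r)
  } else {
    v <- matrix(NA_real_, nrow = length(sched$ages), ncol = length(sched$stages),
                dimnames = list(NULL, sched$stages))
  }
  vxj <- data.frame(age = rep(sched$ages, times = ncol(v)),
                    stage = rep(colnames(v), each = length(sched$ages)),
                    v_xj = as.vector(v), stringsAsFactors = FALSE)
  out <- c(
    summary = write_df(summary_df, out_dir, "summary.csv"),
    parameters = write_df(params_df, out_dir, "parameters.csv"),
    curves_schedule = write_df(curves, out_dir, "curves_schedule.csv"),
    curves_expectancy = write_df(exj, out_dir, "curves_expectancy.csv"),
    curves_value = write_df(vxj, out_dir, "curves_value.csv"))
  invisible(out)
}

#' Compare treatments and write the letters table
#'
#' Pairwise paired bootstrap tests on each requested statistic over two or
#' more cohorts, with the compact letter display.
#'
#' @param inputs Named list of cohorts / paths / preset names (>= 2).
#' @param statistics Character vector of statistic names.
#' @param out_dir Output directory.
#' @param B Replicates.
#' @param seed Integer seed.
#' @return Invisibly, the path of `comparison.csv` (one row per statistic x
#'   treatment: estimate and letter; treatments sharing a letter do not
#'   differ).
#' @export
run_compare <- function(inputs, statistics = c("fecundity", "R0", "r"),
                        out_dir, B = 2000L, seed = 0L) {
  if (length(inputs) < 2) {
    stop_agestage("format", "compare needs at least two cohorts")
  }
  cohorts <- lapply(inputs, resolve_cohort)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- vapply(cohorts, function(c) c$treatment, "")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(statistics, function(st) {
    cmp <- compare_treatments(cohorts, st, B = B, seed = seed)
    data.frame(statistic = st, treatment = cmp$table$treatment,
               estimate = cmp$table$estimate, letter = cmp$table$letter,
               B = B, seed = seed, stringsAsFactors = FALSE)
  })
  invisible(write_df(do.call(rbind, rows), out_dir, "comparison.csv"))
}

#' Simulate a cohort and write it in the interchange CSV dialect
#'
#' @param config A `"synthetic_config"` or a preset name.
#' @param out_dir Output directory.
#' @param seed Integer seed (also logged).
#' @return Invisibly, the paths written (individuals CSV, fecundity CSV and a
#'   small provenance log with the seed and config summary).
#' @export
run_simulate <- function(config, out_dir, seed = 0L) {
  if (is.character(config)) config <- preset_config(config)
  coh <- simulate_cohort(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(config$treatment, ".csv"))
  paths <- write_cohort(coh, path)
  log_path <- file.path(out_dir, paste0(config$treatment, "_config.txt"))
  writeLines(c(
    sprintf("treatment: %s", config$treatment),
    sprintf("n: %d", config$n),
    sprintf("seed: %d", seed),
    sprintf("immature_target: %.4f", config$immature_target),
    sprintf("fecundity_total: %.4f", config$fecundity_total),
    sprintf("peak_age: %s",
            if (is.null(config$peak_age)) "NA"
            else sprintf("%.4f", config$peak_age)),
    sprintf("r_target: %s", format(config$r_target))), log_path)
  invisible(c(paths, log = log_path))
}
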