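#' Default developmental stage ontology
#'
#' The ordered list of life stages used by a daily-census cohort study of a
#' holometabolous predator: egg, four larval instars, pre-pupa, pupa, adult.
#' The last stage is always the reproductive adult stage; in age-stage
#' schedules it is split by sex.
#'
#' @return Character vector of stage names, in developmental order.
#' @export
#' @examples
#' default_stage_ontology()
default_stage_ontology <- function() {
  c("egg", "L1", "L2", "L3", "L4", "prepupa", "pupa", "adult")
}

#' Construct a cohort of individual life-history records
#'
#' A cohort is the unit of analysis: one treatment's set of individually
#' followed animals, censused every 24 h from oviposition (age 0) until death.
#' Each individual carries the number of whole days it spent in every stage it
#' entered; the stage in which it died is recorded with the days survived in
#' that stage, so that `death_age` always equals the sum of its recorded
#' stage durations. Daily egg counts are kept in a long companion table.
#'
#' @param individuals A data.frame with columns `id`, `treatment`, `excluded`
#'   (logical; `TRUE` for e.g. stock-colony replacement males that must never
#'   enter any statistic), `sex` (`"female"`, `"male"` or `"undetermined"`;
#'   the latter only for individuals dying before adulthood), `death_stage`,
#'   `death_age` (integer days since oviposition), and one integer column per
#'   ontology stage giving days spent in that stage (`NA` if never entered).
#' @param fecundity A data.frame with columns `id`, `age_day`, `eggs` giving
#'   the daily egg counts of females, or `NULL` for none.
#' @param treatment Treatment label. Defaults to the value found in
#'   `individuals$treatment`.
#' @param stages Ordered character vector of stage names (the ontology); the
#'   last element is the adult stage.
#' @param census_step Census interval in days; the method assumes 1.
#'
#' @return An object of class `"cohort"`: a list with elements `treatment`,
#'   `stages`, `census_step`, `individuals` and `fecundity`.
#' @seealso [read_cohort()], [write_cohort()], [build_schedule()],
#'   [cohort_summary()]
#' @export
cohort <- function(individuals, fecundity = NULL, treatment = NULL,
                   stages = default_stage_ontology(), census_step = 1) {
  if (is.null(treatment)) {
    treatment <- if (nrow(individuals)) individuals$treatment[[1]] else "unknown"
  }
  if (is.null(fecundity)) {
    fecundity <- data.frame(id = character(), age_day = integer(),
                            eggs = integer(), stringsAsFactors = FALSE)
  }
  individuals <- individuals[order(individuals$id), , drop = FALSE]
  rownames(individuals) <- NULL
  fecundity <- fecundity[order(fecundity$id, fecundity$age_day), , drop = FALSE]
  rownames(fecundity) <- NULL
  obj <- structure(
    list(treatment = treatment, stages = stages, census_step = census_step,
         individuals = individuals, fecundity = fecundity),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks every structural invariant of the data model: stage columns present
#' and in ontology order, recorded stages forming a prefix of the ontology (no
#' skipped stages), `death_stage` equal to the last stage entered,
#' `death_age` equal to the sum of recorded stage durations and at least 1,
#' sex `"undetermined"` only for pre-adult deaths, fecundity only for adult
#' females and only at ages at or after adult emergence.
#'
#' @param x A `"cohort"` object.
#' @return `x`, invisibly. Errors (class `"agestage_validation_error"` or
#'   `"agestage_format_error"`) identify offending rows by id and row number.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ind <- x$individuals
  stages <- x$stages
  required <- c("id", "treatment", "excluded", "sex", "death_stage", "death_age")
  missing_cols <- setdiff(c(required, stages), names(ind))
  if (length(missing_cols)) {
    stop_agestage("format", "individuals table is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ind$id)) {
    stop_agestage("validation", "duplicated individual id(s): ",
                  paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  if (!is.logical(ind$excluded)) {
    stop_agestage("format", "'excluded' must be logical")
  }
  bad_sex <- !ind$sex %in% c("female", "male", "undetermined")
  if (any(bad_sex)) {
    stop_agestage("validation", "invalid sex at row(s) ",
                  paste(which(bad_sex), collapse = ", "))
  }
  dur <- as.matrix(ind[, stages, drop = FALSE])
  storage.mode(dur) <- "double"
  for (i in seq_len(nrow(ind))) {
    d <- dur[i, ]
    entered <- !is.na(d)
    row_lab <- sprintf("row %d (id '%s')", i, ind$id[i])
    if (!any(entered)) {
      stop_agestage("validation", row_lab, ": no stage recorded")
    }
    k <- max(which(entered))
    if (!all(entered[seq_len(k)])) {
      stop_agestage("validation", row_lab,
                    ": recorded stages skip an earlier ontology stage")
    }
    if (any(d[entered] < 1) || any(d[entered] != round(d[entered]))) {
      stop_agestage("validation", row_lab,
                    ": stage durations must be whole days >= 1")
    }
    if (!identical(ind$death_stage[i], stages[k])) {
      stop_agestage("validation", row_lab,
                    ": death_stage '", ind$death_stage[i],
                    "' is not the last recorded stage '", stages[k], "'")
    }
    if (ind$death_age[i] != sum(d[entered])) {
      stop_agestage("validation", row_lab,
                    ": death_age (", ind$death_age[i],
                    ") != sum of recorded stage durations (",
                    sum(d[entered]), ")")
    }
    if (ind$sex[i] == "undetermined" && stages[k] == stages[length(stages)]) {
      stop_agestage("validation", row_lab,
                    ": adults must be sexed (sex is 'undetermined')")
    }
  }
  if (any(ind$death_age < 1)) {
    stop_agestage("validation", "death_age must be >= 1")
  }
  fec <- x$fecundity
  if (nrow(fec)) {
    if (!all(c("id", "age_day", "eggs") %in% names(fec))) {
      stop_agestage("format", "fecundity table needs columns id, age_day, eggs")
    }
    unknown <- setdiff(fec$id, ind$id)
    if (length(unknown)) {
      stop_agestage("validation", "fecundity recorded for unknown id(s): ",
                    paste(unique(unknown), collapse = ", "))
    }
    if (any(fec$eggs < 0) || any(fec$eggs != round(fec$eggs))) {
      stop_agestage("validation", "egg counts must be non-negative integers")
    }
    m <- match(fec$id, ind$id)
    not_female <- ind$sex[m] != "female"
    if (any(not_female)) {
      stop_agestage("validation", "fecundity recorded for non-female id(s): ",
                    paste(unique(fec$id[not_female]), collapse = ", "))
    }
    emergence <- immature_duration(x)[m]
    if (anyNA(emergence)) {
      stop_agestage("validation",
                    "fecundity recorded for individual(s) that never reached ",
                    "the adult stage: ",
                    paste(unique(fec$id[is.na(emergence)]), collapse = ", "))
    }
    early <- fec$age_day < emergence
    if (any(early)) {
      stop_agestage("validation", "fecundity before adult emergence for id(s): ",
                    paste(unique(fec$id[early]), collapse = ", "))
    }
  }
  invisible(x)
}

stop_agestage <- function(kind, ...) {
  cls <- paste0("agestage_", kind, "_error")
  stop(errorCondition(paste0(...), class = c(cls, "agestage_error")))
}

#' Number of analyzable individuals in a cohort
#'
#' @param x A `"cohort"` object.
#' @param excluded If `TRUE`, count excluded individuals too.
#' @return Integer count. Excluded individuals (flagged stock-colony
#'   replacement males) never contribute to any schedule or statistic.
#' @export
cohort_size <- function(x, excluded = FALSE) {
  if (excluded) nrow(x$individuals) else sum(!x$individuals$excluded)
}

# Individuals table restricted to the analyzable set.
active_individuals <- function(x) {
  x$individuals[!x$individuals$excluded, , drop = FALSE]
}

# Fecundity rows of analyzable individuals.
active_fecundity <- function(x) {
  keep <- x$fecundity$id %in% active_individuals(x)$id
  x$fecundity[keep, , drop = FALSE]
}

# Pre-adult (egg through pupa) duration per individual row, NA when the
# individual never completed the pupal stage. Follows individuals order.
immature_duration <- function(x, individuals = x$individuals) {
  stages <- x$stages
  adult <- stages[length(stages)]
  imm <- as.matrix(individuals[, setdiff(stages, adult), drop = FALSE])
  storage.mode(imm) <- "double"
  out <- rowSums(imm)
  out[individuals$death_stage != adult] <- NA_real_
  out
}

#' @export
print.cohort <- function(x, ...) {
  ind <- active_individuals(x)
  adult <- x$stages[length(x$stages)]
  cat(sprintf("<cohort> treatment '%s': %d individuals (%d excluded)\n",
              x$treatment, nrow(ind), nrow(x$individuals) - nrow(ind)))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = " > ")))
  cat(sprintf("  reached adult: %d (%d female / %d male); egg records: %d\n",
              sum(ind$death_stage == adult),
              sum(ind$sex == "female" & ind$death_stage == adult),
              sum(ind$sex == "male" & ind$death_stage == adult),
              nrow(active_fecundity(x))))
  invisible(x)
}

#' Read a cohort from the individual CSV dialect
#'
#' The interchange dialect is one UTF-8 comma-separated file per cohort with
#' one row per individual and columns `id`, `treatment`, `excluded`, `sex`,
#' `death_stage`, `death_age`, then one duration column per ontology stage
#' (empty when the stage was never entered), plus an optional long-format
#' companion file `<stem>_fecundity.csv` with columns `id`, `age_day`, `eggs`.
#'
#' @param path Path to the individuals CSV file.
#' @param fecundity_path Path to the companion fecundity CSV; defaults to
#'   `<stem>_fecundity.csv` next to `path` and is optional (a cohort with no
#'   egg records, e.g. a diet on which no female ever laid, has none).
#' @param format Only `"individual_csv"` is supported.
#' @param stages Stage ontology the file is expected to follow.
#' @return A validated `"cohort"` object.
#' @export
read_cohort <- function(path, fecundity_path = NULL, format = "individual_csv",
                        stages = default_stage_ontology()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_agestage("format", "no such file: ", path)
  }
  ind <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("id", "treatment", "excluded", "sex", "death_stage", "death_age")
  missing_cols <- setdiff(c(required, stages), names(ind))
  if (length(missing_cols)) {
    stop_agestage("format", path, ": missing required column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  ind$excluded <- as.logical(ind$excluded)
  if (anyNA(ind$excluded)) {
    stop_agestage("format", path, ": unparseable 'excluded' at line(s) ",
                  paste(which(is.na(ind$excluded)) + 1L, collapse = ", "))
  }
  for (col in c("death_age", stages)) {
    v <- ind[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      stop_agestage("format", path, ": non-numeric '", col, "' at line(s) ",
                    paste(which(bad) + 1L, collapse = ", "))
    }
    ind[[col]] <- num
  }
  if (is.null(fecundity_path)) {
    fecundity_path <- default_fecundity_path(path)
  }
  fec <- NULL
  if (file.exists(fecundity_path)) {
    fec <- utils::read.csv(fecundity_path, stringsAsFactors = FALSE)
    if (!all(c("id", "age_day", "eggs") %in% names(fec))) {
      stop_agestage("format", fecundity_path,
                    ": fecundity file needs columns id, age_day, eggs")
    }
  }
  cohort(ind, fec, stages = stages)
}

default_fecundity_path <- function(path) {
  sub("\\.csv$", "_fecundity.csv", path)
}

#' Write a cohort in the individual CSV dialect
#'
#' Output is deterministic and lossless: fixed column order, rows sorted by
#' `id`, integer day counts, empty cells for stages never entered. Reading a
#' written file back and writing it again produces byte-identical files.
#'
#' @param x A `"cohort"` object.
#' @param path Output path for the individuals CSV.
#' @param fecundity_path Output path for the companion fecundity CSV; defaults
#'   to `<stem>_fecundity.csv`. Written even when empty (header only).
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_cohort <- function(x, path, fecundity_path = NULL) {
  validate_cohort(x)
  if (is.null(fecundity_path)) {
    fecundity_path <- default_fecundity_path(path)
  }
  ind <- x$individuals[order(x$individuals$id), , drop = FALSE]
  cols <- c("id", "treatment", "excluded", "sex", "death_stage", "death_age",
            x$stages)
  ind <- ind[, cols, drop = FALSE]
  for (col in c("death_age", x$stages)) {
    ind[[col]] <- ifelse(is.na(ind[[col]]), "",
                         format(as.integer(ind[[col]]), scientific = FALSE,
                                trim = TRUE))
  }
  ind$excluded <- ifelse(ind$excluded, "TRUE", "FALSE")
  utils::write.csv(ind, path, row.names = FALSE, quote = FALSE)
  fec <- x$fecundity[order(x$fecundity$id, x$fecundity$age_day), , drop = FALSE]
  fec <- fec[, c("id", "age_day", "eggs"), drop = FALSE]
  fec$age_day <- as.integer(fec$age_day)
  fec$eggs <- as.integer(fec$eggs)
  utils::write.csv(fec, fecundity_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, fecundity_path))
}
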