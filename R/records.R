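#' Read longitudinal breeding records from CSV
#'
#' Reads a table of one row per individual x breeding season and validates it.
#' The file must have a header naming the seven columns
#' `individual_id, population, cohort, season, age, primiparous, success`;
#' booleans are coded 0/1. Seasons are labelled by the starting calendar year
#' of the breeding season and `age = season - cohort` (cohort = fledge year).
#'
#' @param path Path to a CSV file.
#' @param final_season Final season of the study. Defaults to the maximum
#'   season present in the file; carried as the `study_final_season`
#'   attribute and used by [mark_presumed_dead()].
#' @return A tibble of validated breeding records with attribute
#'   `study_final_season`.
#' @seealso [validate_breeding_records()], [write_breeding_records()]
#' @export
read_breeding_records <- function(path, final_season = NULL) {
  if (!file.exists(path)) abort(paste0("records file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("individual_id", "population", "cohort", "season", "age",
                "primiparous", "success")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("format error: missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- x[required]
  x$primiparous <- dplyr::recode(x$primiparous, "TRUE" = "1", "FALSE" = "0",
                                 .default = x$primiparous)
  for (col in c("cohort", "season", "age", "primiparous", "success")) {
    v <- x[[col]]
    bad <- which(is.na(v) | is.na(suppressWarnings(as.numeric(v))) |
                   suppressWarnings(as.numeric(v)) %% 1 != 0)
    if (length(bad)) {
      abort(paste0("parse error: non-integer ", col, " at row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    x[[col]] <- as.integer(v)
  }
  x$primiparous <- x$primiparous == 1L
  records <- as_tibble(x)
  validate_breeding_records(records)
  attr(records, "study_final_season") <-
    if (is.null(final_season)) max(records$season) else as.integer(final_season)
  records
}

#' Validate a breeding-record table
#'
#' Checks the record invariants: non-negative age, `age == season - cohort`,
#' one record per (individual, season), success in 0/1, one population per
#' individual, and primiparity flagged only on an individual's earliest
#' season. Violations raise errors naming the offending rows.
#'
#' @param records A breeding-record data frame.
#' @return `records`, invisibly, if valid.
#' @export
validate_breeding_records <- function(records) {
  stopifnot(is.data.frame(records))
  bad_age <- which(records$age < 0L)
  if (length(bad_age)) {
    abort(paste0("validation error: negative age at row(s) ",
                 paste(head(bad_age, 5), collapse = ", ")))
  }
  mism <- which(records$age != records$season - records$cohort)
  if (length(mism)) {
    abort(paste0("validation error: age != season - cohort at row(s) ",
                 paste(head(mism, 5), collapse = ", ")))
  }
  key <- paste(records$individual_id, records$season)
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(paste0("validation error: duplicate (individual_id, season) at row(s) ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  bad_succ <- which(!records$success %in% c(0L, 1L))
  if (length(bad_succ)) {
    abort(paste0("validation error: success not 0/1 at row(s) ",
                 paste(head(bad_succ, 5), collapse = ", ")))
  }
  npop <- tapply(records$population, records$individual_id,
                 function(p) length(unique(p)))
  if (any(npop > 1)) {
    abort(paste0("validation error: individual(s) in more than one population: ",
                 paste(head(names(npop)[npop > 1], 5), collapse = ", ")))
  }
  first_season <- tapply(records$season, records$individual_id, min)
  primi_bad <- which(records$primiparous &
                       records$season != first_season[records$individual_id])
  if (length(primi_bad)) {
    abort(paste0("validation error: primiparous flagged after first season at row(s) ",
                 paste(head(primi_bad, 5), collapse = ", ")))
  }
  invisible(records)
}

#' Write breeding records to CSV
#'
#' @param records A breeding-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_breeding_records <- function(records, path) {
  out <- records
  out$primiparous <- as.integer(out$primiparous)
  readr::write_csv(out, path)
  invisible(path)
}

final_season_of <- function(records, final_season = NULL) {
  if (!is.null(final_season)) return(as.integer(final_season))
  fs <- attr(records, "study_final_season")
  if (!is.null(fs)) as.integer(fs) else max(records$season)
}

keep_attrs <- function(new, old) {
  attr(new, "study_final_season") <- attr(old, "study_final_season")
  new
}

#' Drop individuals that first bred at or above an age threshold
#'
#' Individuals whose earliest observed breeding age is `max_age` or older are
#' removed entirely (all their records); typically these are ring-reading
#' errors or chronic nonbreeders in long-lived seabirds.
#'
#' @param records A breeding-record tibble.
#' @param max_age First-breeding age threshold in years (default 20): an
#'   individual is kept only if it first bred strictly before this age.
#' @return The filtered tibble.
#' @export
filter_first_breeding_age <- function(records, max_age = 20) {
  first <- records |>
    group_by(.data$individual_id) |>
    summarise(first_age = min(.data$age), .groups = "drop")
  keep <- first$individual_id[first$first_age < max_age]
  keep_attrs(records[records$individual_id %in% keep, , drop = FALSE], records)
}

#' Flag individuals presumed dead at the end of the study
#'
#' An individual is presumed dead if it was not seen during the final `gap`
#' breeding seasons of the study (inclusive of the final season), i.e. its
#' last observed season is `< final_season - (gap - 1)`. Established breeders
#' are highly site-faithful and rarely skip more than three consecutive
#' seasons, so a four-season absence is taken as death.
#'
#' @param records A breeding-record tibble.
#' @param gap Number of final seasons of absence implying death (default 4).
#' @param final_season Final season of the study; defaults to the table's
#'   `study_final_season` attribute (or its maximum season).
#' @return A tibble with one row per individual: `individual_id`,
#'   `population`, `last_season`, `presumed_dead`.
#' @export
mark_presumed_dead <- function(records, gap = 4, final_season = NULL) {
  if (gap < 1) abort("parameter error: gap must be >= 1")
  fs <- final_season_of(records, final_season)
  records |>
    group_by(.data$individual_id, .data$population) |>
    summarise(last_season = max(.data$season), .groups = "drop") |>
    mutate(presumed_dead = .data$last_season < fs - (gap - 1))
}

#' Keep individuals with at least k breeding attempts
#'
#' Robustness subset: restricts to individuals recorded breeding at least
#' `k` times during the study period.
#'
#' @param records A breeding-record tibble.
#' @param k Minimum number of records per individual (default 4).
#' @return The filtered tibble.
#' @export
subset_min_attempts <- function(records, k = 4) {
  if (k < 1) abort("parameter error: k must be >= 1")
  counts <- table(records$individual_id)
  keep <- names(counts)[counts >= k]
  keep_attrs(records[records$individual_id %in% keep, , drop = FALSE], records)
}

#' Subset to the fitness cohort (fledged early, presumed dead)
#'
#' Keeps individuals fledged before `cohort_before` and (optionally) presumed
#' dead by the end of the study, so that lifetime reproductive success is
#' complete rather than right-censored.
#'
#' @param records A breeding-record tibble.
#' @param dead_flags Per-individual flags from [mark_presumed_dead()];
#'   required when `dead_only = TRUE`.
#' @param cohort_before Keep cohorts strictly before this fledge year
#'   (default 2000).
#' @param dead_only If `TRUE` (default), additionally require
#'   `presumed_dead`.
#' @return The filtered tibble.
#' @export
subset_fitness_cohort <- function(records, dead_flags = NULL,
                                  cohort_before = 2000, dead_only = TRUE) {
  out <- records[records$cohort < cohort_before, , drop = FALSE]
  if (dead_only) {
    if (is.null(dead_flags)) {
      abort("state error: dead_flags required when dead_only = TRUE; run mark_presumed_dead() first")
    }
    dead_ids <- dead_flags$individual_id[dead_flags$presumed_dead]
    out <- out[out$individual_id %in% dead_ids, , drop = FALSE]
  }
  keep_attrs(out, records)
}

#' Per-individual lifetime reproductive outputs
#'
#' Lifetime reproductive success (LRS) is the total number of successful
#' breeding attempts (chicks fledged) over an individual's recorded life;
#' `n_attempts` is its number of recorded breeding attempts.
#'
#' @param records A breeding-record tibble.
#' @return A tibble with one row per individual: `individual_id`,
#'   `population`, `cohort`, `lrs`, `n_attempts`.
#' @export
compute_lifetime_outputs <- function(records) {
  records |>
    group_by(.data$individual_id, .data$population, .data$cohort) |>
    summarise(lrs = sum(.data$success), n_attempts = n(), .groups = "drop")
}
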