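# Readers/writers for the OMOP-lite CSV dialect and the episode table.
# Identifiers are opaque strings; dates are calendar dates (ISO-8601) and
# all arithmetic downstream is in whole days.

EVENT_TABLES <- c(
  condition_occurrence = "condition",
  procedure_occurrence = "procedure",
  observation = "observation",
  drug_exposure = "drug"
)

read_csv_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = TRUE)
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in table '%s': missing column(s) %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

parse_date_column <- function(x, table, column) {
  x <- trimws(x)
  d <- as.Date(rep(NA_character_, length(x)))
  nonempty <- !is.na(x) & nzchar(x)
  ok_format <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[nonempty])
  parsed <- as.Date(x[nonempty], format = "%Y-%m-%d")
  bad <- which(nonempty)[!ok_format | is.na(parsed)]
  if (length(bad)) {
    stop(sprintf(
      "date parse error in table '%s', column '%s': row(s) %s (value(s) %s) are not ISO-8601 dates",
      table, column,
      paste(utils::head(bad, 5), collapse = ", "),
      paste(sQuote(utils::head(x[bad], 5)), collapse = ", ")
    ), call. = FALSE)
  }
  d[nonempty] <- parsed
  d
}

empty_events <- function() {
  data.frame(person_id = character(0), concept_id = character(0),
             domain = character(0), event_date = as.Date(character(0)),
             value = numeric(0), unit = character(0),
             stringsAsFactors = FALSE)
}

#' Read an OMOP-lite cohort from CSV tables
#'
#' Reads `person.csv`, `observation_period.csv` and any of the four event
#' tables (`condition_occurrence.csv`, `procedure_occurrence.csv`,
#' `observation.csv`, `drug_exposure.csv`) from a directory, or from an
#' explicit named list of paths. Duplicate event rows are preserved: repeat
#' billings carry meaning for the algorithm.
#'
#' @param dir Directory containing the CSV tables, or `NULL` when `paths`
#'   is given.
#' @param paths Optional named list/vector of file paths keyed by table name
#'   (`person`, `observation_period`, `condition_occurrence`, ...).
#' @return A list of class `preg_cohort` with data frames `persons`
#'   (`person_id`, `sex`, `birth_date`), `observation_periods` (`person_id`,
#'   `period_start`, `period_end`) and `events` (`person_id`, `concept_id`,
#'   `domain`, `event_date`, `value`, `unit`), plus `ground_truth` if a
#'   `ground_truth.csv` is present (as written by the simulator).
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("provide either dir or paths")
    files <- c("person", "observation_period", names(EVENT_TABLES), "ground_truth")
    paths <- file.path(dir, paste0(files, ".csv"))
    names(paths) <- files
    paths <- paths[file.exists(paths)]
  }
  paths <- as.list(paths)
  for (req in c("person", "observation_period")) {
    if (is.null(paths[[req]])) stop("missing required table: ", req)
    if (!file.exists(paths[[req]])) stop("file not found: ", paths[[req]])
  }

  persons <- read_csv_table(paths$person)
  require_columns(persons, c("person_id", "sex", "birth_date"), "person")
  persons$birth_date <- parse_date_column(persons$birth_date, "person", "birth_date")
  persons <- persons[, c("person_id", "sex", "birth_date")]

  periods <- read_csv_table(paths$observation_period)
  require_columns(periods, c("person_id", "period_start", "period_end"),
                  "observation_period")
  periods$period_start <- parse_date_column(periods$period_start,
                                            "observation_period", "period_start")
  periods$period_end <- parse_date_column(periods$period_end,
                                          "observation_period", "period_end")
  periods <- periods[, c("person_id", "period_start", "period_end")]

  events <- list()
  for (tbl in names(EVENT_TABLES)) {
    if (is.null(paths[[tbl]])) next
    df <- read_csv_table(paths[[tbl]])
    require_columns(df, c("person_id", "concept_id", "event_date"), tbl)
    df$event_date <- parse_date_column(df$event_date, tbl, "event_date")
    df$domain <- rep(EVENT_TABLES[[tbl]], nrow(df))
    df$value <- if ("value" %in% names(df)) {
      suppressWarnings(as.numeric(df$value))
    } else rep(NA_real_, nrow(df))
    df$unit <- if ("unit" %in% names(df)) df$unit else rep(NA_character_, nrow(df))
    events[[tbl]] <- df[, c("person_id", "concept_id", "domain", "event_date",
                            "value", "unit")]
  }
  events <- if (length(events)) do.call(rbind, c(events, make.row.names = FALSE)) else empty_events()

  out <- list(persons = persons, observation_periods = periods, events = events)
  if (!is.null(paths$ground_truth) && file.exists(paths$ground_truth)) {
    gt <- read_csv_table(paths$ground_truth)
    if ("episode" %in% names(gt)) gt$episode <- as.integer(gt$episode)
    gt$true_start_date <- parse_date_column(gt$true_start_date, "ground_truth",
                                            "true_start_date")
    gt$true_outcome_date <- parse_date_column(gt$true_outcome_date, "ground_truth",
                                              "true_outcome_date")
    out$ground_truth <- gt
  }
  class(out) <- "preg_cohort"
  out
}

#' Validate a cohort
#'
#' Checks structural invariants: unique person identifiers, ordered and
#' non-overlapping observation periods per person, and (as a warning, not an
#' error) events dated outside every observation period of their person.
#'
#' @param cohort A `preg_cohort` list.
#' @return The cohort, invisibly; problems raise errors or warnings.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$persons
  if (anyDuplicated(p$person_id)) {
    stop("person_id values must be unique within a cohort")
  }
  op <- cohort$observation_periods
  if (any(op$period_start > op$period_end)) {
    stop("observation periods require period_start <= period_end")
  }
  if (nrow(op) > 1) {
    for (pid in unique(op$person_id[duplicated(op$person_id)])) {
      sub <- op[op$person_id == pid, ]
      sub <- sub[order(sub$period_start), ]
      if (any(utils::head(sub$period_end, -1) >= utils::tail(sub$period_start, -1))) {
        stop("overlapping observation periods for person ", pid)
      }
    }
  }
  ev <- cohort$events
  if (nrow(ev)) {
    covered <- vapply(seq_len(nrow(ev)), function(i) {
      any(op$person_id == ev$person_id[i] &
            op$period_start <= ev$event_date[i] &
            op$period_end >= ev$event_date[i])
    }, logical(1))
    if (any(!covered)) {
      warning(sum(!covered),
              " event(s) dated outside every observation period of their person")
    }
  }
  invisible(cohort)
}

fmt_date <- function(d) format(d, "%Y-%m-%d")

#' Write a cohort to CSV tables
#'
#' Inverse of [read_cohort()]: writes `person.csv`, `observation_period.csv`,
#' the four event tables split by domain, and `ground_truth.csv` when
#' present. Dates are serialised as ISO-8601.
#'
#' @param cohort A `preg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$persons
  p$birth_date <- fmt_date(p$birth_date)
  utils::write.csv(p, file.path(dir, "person.csv"), row.names = FALSE)
  op <- cohort$observation_periods
  op$period_start <- fmt_date(op$period_start)
  op$period_end <- fmt_date(op$period_end)
  utils::write.csv(op, file.path(dir, "observation_period.csv"), row.names = FALSE)
  ev <- cohort$events
  for (tbl in names(EVENT_TABLES)) {
    sub <- ev[ev$domain == EVENT_TABLES[[tbl]],
              c("person_id", "concept_id", "event_date", "value", "unit")]
    sub$event_date <- fmt_date(sub$event_date)
    utils::write.csv(sub, file.path(dir, paste0(tbl, ".csv")), row.names = FALSE)
  }
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$true_start_date <- fmt_date(gt$true_start_date)
    gt$true_outcome_date <- fmt_date(gt$true_outcome_date)
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

EPISODE_COLUMNS <- c("person_id", "episode_index", "outcome_class",
                     "outcome_date", "start_date", "start_method",
                     "term_status", "clamped", "adjusted")

#' Write / read the pregnancy episode table
#'
#' One row per finalized episode with all fields (person, ordinal index,
#' outcome class and date, start date and method, term status and the
#' clamp/adjustment flags). Writing then reading yields an identical table.
#'
#' @param episodes Episode data frame as produced by [build_episodes()].
#' @param path CSV file path.
#' @return `write_episodes` returns `path` invisibly; `read_episodes`
#'   returns the episode data frame with proper column types.
#' @export
write_episodes <- function(episodes, path) {
  stopifnot(all(EPISODE_COLUMNS %in% names(episodes)))
  out <- episodes[, EPISODE_COLUMNS]
  out$outcome_date <- fmt_date(out$outcome_date)
  out$start_date <- fmt_date(out$start_date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, EPISODE_COLUMNS, "pregnancy_episodes")
  df$episode_index <- as.integer(df$episode_index)
  df$outcome_date <- parse_date_column(df$outcome_date, "pregnancy_episodes",
                                       "outcome_date")
  df$start_date <- parse_date_column(df$start_date, "pregnancy_episodes",
                                     "start_date")
  df$clamped <- as.logical(df$clamped)
  df$adjusted <- as.logical(df$adjusted)
  df[, EPISODE_COLUMNS]
}

age_at <- function(birth_date, date) {
  # Completed years of age at `date`.
  b <- as.POSIXlt(birth_date)
  d <- as.POSIXlt(date)
  age <- d$year - b$year
  before_birthday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  age - as.integer(before_birthday)
}
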