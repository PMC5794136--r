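# Concept catalog: map concept identifiers to algorithm categories, and the
# disproportionality screen used to curate ectopic-associated concepts.

#' Load concept sets from CSV
#'
#' Reads a two-column table (`concept_id`, `category`) mapping opaque
#' concept identifiers to algorithm categories. Unknown category names and
#' conflicting duplicate assignments are errors; concept identifiers absent
#' from the table are simply uncategorized and invisible to the algorithm.
#'
#' @param path CSV file with columns `concept_id` and `category`.
#' @return A data frame of class `concept_set` with one row per concept.
#' @export
load_concept_sets <- function(path) {
  df <- read_csv_table(path)
  require_columns(df, c("concept_id", "category"), "concept_sets")
  as_concept_set(df[, c("concept_id", "category")])
}

as_concept_set <- function(df) {
  valid <- c(OUTCOME_CATEGORIES, MARKER_CATEGORIES)
  bad <- setdiff(unique(df$category), valid)
  if (length(bad)) {
    stop("unknown category name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$concept_id[duplicated(df$concept_id)])
  if (length(dup)) {
    for (id in dup) {
      cats <- unique(df$category[df$concept_id == id])
      if (length(cats) > 1) {
        stop("concept_id '", id, "' mapped to conflicting categories: ",
             paste(cats, collapse = ", "), call. = FALSE)
      }
    }
    df <- df[!duplicated(df$concept_id), ]
  }
  rownames(df) <- NULL
  class(df) <- c("concept_set", "data.frame")
  df
}

#' Annotate events with their algorithm category
#'
#' Adds a `category` column to the event table by looking each
#' `concept_id` up in the concept set; events whose concept is not in the
#' set get `NA` (uncategorized) and are ignored downstream. The number and
#' order of rows is unchanged.
#'
#' @param events Event data frame (see [read_cohort()]).
#' @param concept_set A `concept_set` as from [load_concept_sets()].
#' @return `events` with an added/overwritten `category` column.
#' @export
categorize_events <- function(events, concept_set) {
  idx <- match(events$concept_id, concept_set$concept_id)
  events$category <- concept_set$category[idx]
  events
}

#' Disproportionality screen for ectopic-associated concepts
#'
#' Curates concepts whose prevalence in the 60 days following an ectopic
#' pregnancy diagnosis is disproportionately high relative to a reference
#' female population. Reference prevalence is person-level: the proportion
#' of women in `age_range` (at mid reference year) observed for the whole
#' reference calendar year who have at least one record of the concept
#' dated in that year. Ectopic prevalence is window-level: the proportion
#' of diagnosis windows `[diagnosis, diagnosis + episode_window_days]`
#' containing at least one record of the concept.
#'
#' @param events Categorized event table (ectopic diagnoses are the rows
#'   with `category == "ectopic"`).
#' @param persons Person table.
#' @param observation_periods Observation-period table (full-year coverage
#'   is required for reference eligibility).
#' @param reference_year Calendar year of the reference population.
#' @param age_range Inclusive age bounds at July 1 of the reference year;
#'   default `c(15, 55)`.
#' @param episode_window_days Closed post-diagnosis window length; default 60.
#' @param pr_threshold Minimum prevalence ratio for inclusion; default 5.
#' @return Data frame (`concept_id`, `prevalence_ref`, `prevalence_ect`,
#'   `ratio`, `infinite_ratio`) of concepts whose ratio exceeds
#'   `pr_threshold`, including those with zero reference prevalence but
#'   nonzero ectopic-window prevalence (flagged `infinite_ratio`).
#' @export
ectopic_disproportionality <- function(events, persons, observation_periods,
                                       reference_year,
                                       age_range = c(15L, 55L),
                                       episode_window_days = 60L,
                                       pr_threshold = 5) {
  if (!"category" %in% names(events)) {
    stop("events must be categorized first (see categorize_events)")
  }
  year_start <- as.Date(sprintf("%d-01-01", reference_year))
  year_end <- as.Date(sprintf("%d-12-31", reference_year))
  mid_year <- as.Date(sprintf("%d-07-01", reference_year))

  op <- observation_periods
  full_year <- unique(op$person_id[op$period_start <= year_start &
                                     op$period_end >= year_end])
  ref <- persons[persons$sex == "female" & persons$person_id %in% full_year, ]
  if (nrow(ref)) {
    ages <- age_at(ref$birth_date, mid_year)
    ref <- ref[ages >= age_range[1] & ages <= age_range[2], ]
  }
  n_ref <- nrow(ref)
  if (n_ref == 0) {
    stop("no eligible reference women: prevalence ratio undefined")
  }

  ect <- events[!is.na(events$category) & events$category == "ectopic", ]
  windows <- ect[, c("person_id", "event_date")]
  n_win <- nrow(windows)

  concepts <- sort(unique(events$concept_id))
  prevalence_ref <- numeric(length(concepts))
  prevalence_ect <- numeric(length(concepts))
  in_year <- events$event_date >= year_start & events$event_date <= year_end
  for (k in seq_along(concepts)) {
    rows <- events$concept_id == concepts[k]
    with_rec <- unique(events$person_id[rows & in_year])
    prevalence_ref[k] <- sum(ref$person_id %in% with_rec) / n_ref
    if (n_win) {
      hit <- vapply(seq_len(n_win), function(i) {
        any(rows &
              events$person_id == windows$person_id[i] &
              events$event_date >= windows$event_date[i] &
              events$event_date <= windows$event_date[i] + episode_window_days)
      }, logical(1))
      prevalence_ect[k] <- sum(hit) / n_win
    }
  }
  ratio <- ifelse(prevalence_ref > 0, prevalence_ect / prevalence_ref, Inf)
  keep <- (prevalence_ref > 0 & ratio > pr_threshold) |
    (prevalence_ref == 0 & prevalence_ect > 0)
  out <- data.frame(
    concept_id = concepts[keep],
    prevalence_ref = prevalence_ref[keep],
    prevalence_ect = prevalence_ect[keep],
    ratio = ratio[keep],
    infinite_ratio = prevalence_ref[keep] == 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
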