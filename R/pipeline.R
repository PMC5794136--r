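# Orchestration: categorize -> classify -> estimate -> include, per person,
# over a whole cohort.

empty_episodes <- function() {
  data.frame(person_id = character(0), episode_index = integer(0),
             outcome_class = character(0),
             outcome_date = as.Date(character(0)),
             start_date = as.Date(character(0)),
             start_method = character(0), term_status = character(0),
             clamped = logical(0), adjusted = logical(0),
             stringsAsFactors = FALSE)
}

EXCLUSION_REASONS <- c("not_female", "age_out_of_range", "enrollment_gap",
                       "fewer_than_two_markers")

#' Build pregnancy episodes for a cohort
#'
#' Runs the full algorithm: events are categorized against the concept set;
#' per person, outcomes are classified through the hierarchy and a start
#' date is estimated for each accepted outcome in date order (the prior
#' outcome of each episode is the accepted outcome immediately before it).
#' Inclusion criteria are then applied per candidate episode: the person is
#' female; age at episode start is within `config$age_range` (12-55);
#' one observation period covers the episode from start through outcome
#' (continuous enrollment); and at least `config$min_markers` categorized
#' pregnancy events (outcome or marker categories) are dated inside
#' `[start, outcome]` — the outcome record itself counts unless
#' `count_outcome_record` is disabled. Persons are processed independently:
#' a failure in one person's data aborts only that person (with a warning).
#'
#' @param cohort A `preg_cohort` (see [read_cohort()] / [generate_cohort()]).
#' @param concept_set A `concept_set` mapping concepts to categories.
#' @param config A [pregepi_config()].
#' @return List with `episodes` (one row per included episode, indexed per
#'   person in date order) and `report`, the inclusion report: `total`
#'   candidate episodes, `included`, and counts excluded by each criterion
#'   (`not_female`, `age_out_of_range`, `enrollment_gap`,
#'   `fewer_than_two_markers`; the first failing criterion in that order is
#'   charged).
#' @export
build_episodes <- function(cohort, concept_set, config = pregepi_config()) {
  events <- categorize_events(cohort$events, concept_set)
  persons <- cohort$persons
  periods <- cohort$observation_periods

  report <- stats::setNames(as.list(rep(0L, length(EXCLUSION_REASONS))),
                            EXCLUSION_REASONS)
  report$total <- 0L
  report$included <- 0L

  ev_split <- split(seq_len(nrow(events)), events$person_id)
  out <- list()

  for (pid in persons$person_id) {
    idx <- ev_split[[pid]]
    if (is.null(idx)) next
    pe <- events[idx, , drop = FALSE]
    pe <- pe[!is.na(pe$category), , drop = FALSE]
    if (!nrow(pe)) next
    person <- persons[persons$person_id == pid, ]
    pp <- periods[periods$person_id == pid, , drop = FALSE]

    res <- tryCatch(
      person_episodes(pid, person, pp, pe, config),
      error = function(e) {
        warning("person ", pid, " skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) next
    report$total <- report$total + res$total
    report$included <- report$included + res$included
    for (r in EXCLUSION_REASONS) report[[r]] <- report[[r]] + res$excluded[[r]]
    if (!is.null(res$episodes)) out[[pid]] <- res$episodes
  }

  episodes <- if (length(out)) {
    do.call(rbind, c(out, make.row.names = FALSE))
  } else {
    empty_episodes()
  }
  list(episodes = episodes, report = report)
}

person_episodes <- function(pid, person, periods, pe, config) {
  accepted <- classify_outcomes(pe, config)
  excluded <- stats::setNames(as.list(rep(0L, length(EXCLUSION_REASONS))),
                              EXCLUSION_REASONS)
  n <- nrow(accepted)
  if (!n) {
    return(list(total = 0L, included = 0L, excluded = excluded, episodes = NULL))
  }

  rows <- list()
  prior <- NULL
  for (i in seq_len(n)) {
    cls <- accepted$outcome_class[i]
    od <- accepted$final_date[i]
    est <- estimate_start(cls, od, pe, config, prior)
    rows[[i]] <- data.frame(
      person_id = pid, episode_index = NA_integer_, outcome_class = cls,
      outcome_date = od, start_date = est$start_date,
      start_method = est$start_method, term_status = est$term_status,
      clamped = est$clamped, adjusted = est$adjusted,
      stringsAsFactors = FALSE
    )
    prior <- list(outcome_class = cls, final_date = od)
  }
  cand <- do.call(rbind, c(rows, make.row.names = FALSE))

  keep <- logical(n)
  for (i in seq_len(n)) {
    start <- cand$start_date[i]
    od <- cand$outcome_date[i]
    if (person$sex != "female") {
      excluded$not_female <- excluded$not_female + 1L
    } else if ({
      age <- age_at(person$birth_date, start)
      age < config$age_range[1] || age > config$age_range[2]
    }) {
      excluded$age_out_of_range <- excluded$age_out_of_range + 1L
    } else if (!any(periods$period_start <= start & periods$period_end >= od)) {
      excluded$enrollment_gap <- excluded$enrollment_gap + 1L
    } else {
      in_win <- pe$event_date >= start & pe$event_date <= od
      n_ev <- if (config$count_outcome_record) {
        sum(in_win)
      } else {
        sum(in_win & pe$category %in% MARKER_CATEGORIES)
      }
      if (n_ev < config$min_markers) {
        excluded$fewer_than_two_markers <- excluded$fewer_than_two_markers + 1L
      } else {
        keep[i] <- TRUE
      }
    }
  }

  eps <- cand[keep, , drop = FALSE]
  if (nrow(eps)) {
    eps <- eps[order(eps$outcome_date), , drop = FALSE]
    eps$episode_index <- seq_len(nrow(eps))
  } else {
    eps <- NULL
  }
  list(total = n, included = sum(keep), excluded = excluded, episodes = eps)
}
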