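# Step 2: start date estimation. For each accepted outcome the highest
# ranked eligible start marker determines the start (marker date minus its
# offset); failing that, an outcome- and term-specific average gestational
# age is subtracted from the outcome date. The start is clamped to the
# prior outcome's retry period, and low-confidence starts (amenorrhea,
# urine test, average estimate) are adjusted against contraceptive exposure
# and pregnancy-confirmation records.

retry_days_for <- function(cfg, outcome_class) {
  term_window_for(cfg, outcome_class)$retry_days
}

retry_floor <- function(cfg, prior) {
  if (is.null(prior)) return(NULL)
  prior$final_date + retry_days_for(cfg, prior$outcome_class)
}

#' Eligible start markers for an outcome
#'
#' A marker is eligible when its implied start `s` (marker date minus the
#' hierarchy offset; for gestational-age records, minus the recorded
#' gestational age converted to days) yields a term length strictly between
#' the outcome's minimum and maximum term (`min_term < outcome - s <
#' max_term`), the marker record itself lies in the backward search window
#' `[outcome - max_term, outcome]`, and — when a prior outcome exists — the
#' marker is not dated before the prior outcome date plus its retry period.
#'
#' @param outcome_class Outcome class of the episode.
#' @param outcome_date Final outcome date.
#' @param events Categorized event table for the person.
#' @param config A [pregepi_config()].
#' @param prior Optional prior outcome: list/row with `outcome_class` and
#'   `final_date`.
#' @return Data frame (`rank`, `category`, `method`, `event_date`,
#'   `implied_start`, `term_days`) sorted by rank then event date.
#' @export
eligible_markers <- function(outcome_class, outcome_date, events,
                             config = pregepi_config(), prior = NULL) {
  tw <- term_window_for(config, outcome_class)
  win_lo <- outcome_date - tw$max_term_days
  floor_date <- retry_floor(config, prior)

  hy <- config$hierarchy
  out <- list()
  for (r in seq_len(nrow(hy))) {
    cat <- hy$category[r]
    rows <- which(!is.na(events$category) & events$category == cat &
                    events$event_date >= win_lo &
                    events$event_date <= outcome_date)
    if (!length(rows)) next
    ed <- events$event_date[rows]
    if (cat == "gest_age") {
      val <- events$value[rows]
      unit <- if ("unit" %in% names(events)) events$unit[rows] else rep(NA_character_, length(rows))
      days <- ifelse(!is.na(unit) & unit == "days", val, val * 7)
      keep <- !is.na(days) & days >= 0
      ed <- ed[keep]
      days <- days[keep]
      implied <- ed - as.integer(round(days))
    } else {
      implied <- ed - hy$offset_days[r]
    }
    if (!length(ed)) next
    term <- as.integer(outcome_date - implied)
    elig <- term > tw$min_term_days & term < tw$max_term_days
    if (!is.null(floor_date)) elig <- elig & ed >= floor_date
    if (!any(elig)) next
    out[[length(out) + 1]] <- data.frame(
      rank = r, category = cat, method = hy$method[r],
      event_date = ed[elig], implied_start = implied[elig],
      term_days = term[elig], stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(rank = integer(0), category = character(0),
                      method = character(0),
                      event_date = as.Date(character(0)),
                      implied_start = as.Date(character(0)),
                      term_days = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$rank, res$event_date, res$implied_start), ]
  rownames(res) <- NULL
  res
}

#' Estimate the start date of one pregnancy episode
#'
#' Picks the highest-ranked marker category with at least one eligible
#' event; within that category the earliest eligible event (configurable)
#' supplies the implied start. With no eligible marker the episode falls
#' back to the average gestational-age estimate: it is classified preterm
#' when a preterm-category record lies in the search window, full-term
#' otherwise, and the corresponding estimate is subtracted from the outcome
#' date. If the prior outcome date plus its retry period is later than the
#' estimated start, the start is clamped to that date. Starts produced by
#' amenorrhea, urine-test or average-estimate methods are finally passed
#' through [adjust_start()].
#'
#' @inheritParams eligible_markers
#' @return List with `start_date`, `start_method`, `term_status`
#'   (`not_applicable` for marker-based starts), `clamped` and `adjusted`.
#' @export
estimate_start <- function(outcome_class, outcome_date, events,
                           config = pregepi_config(), prior = NULL) {
  tw <- term_window_for(config, outcome_class)
  floor_date <- retry_floor(config, prior)
  markers <- eligible_markers(outcome_class, outcome_date, events, config, prior)

  if (nrow(markers)) {
    top <- markers[markers$rank == markers$rank[1], ]
    pick <- if (config$within_category_pick == "earliest") 1L else nrow(top)
    start <- top$implied_start[pick]
    method <- top$method[pick]
    term_status <- "not_applicable"
  } else {
    win_lo <- outcome_date - tw$max_term_days
    pre <- !is.na(events$category) & events$category == "preterm" &
      events$event_date >= win_lo & events$event_date <= outcome_date
    if (!is.null(floor_date)) pre <- pre & events$event_date >= floor_date
    term_status <- if (any(pre)) "preterm" else "full_term"
    cls <- if (outcome_class == "delivery") "live_birth" else outcome_class
    est <- config$gestational_estimates[cls, term_status]
    start <- outcome_date - est
    method <- "outcome_estimate"
  }

  clamped <- FALSE
  if (!is.null(floor_date) && floor_date > start) {
    start <- floor_date
    clamped <- TRUE
  }

  adjusted <- FALSE
  if (method %in% c("amenorrhea", "urine_test", "outcome_estimate")) {
    adj <- adjust_start(start, method, outcome_class, outcome_date, events,
                        config, floor_date = floor_date)
    adjusted <- adj$adjusted
    start <- adj$start_date
  }

  list(start_date = start, start_method = method, term_status = term_status,
       clamped = clamped, adjusted = adjusted)
}

#' Adjust low-confidence start dates
#'
#' Reconstructed refinement applied only to starts estimated with
#' amenorrhea, urine pregnancy test or the average gestational-age
#' estimate: (a) a contraceptive drug exposure dated after the estimated
#' start but more than a minimum term before the outcome contradicts the
#' estimate, so the start moves to the day after the last such exposure;
#' (b) when the earliest pregnancy-confirmation record precedes the
#' estimated start, the start moves to the confirmation date minus
#' `confirmation_lead_days` (default 28). An adjustment that would push the
#' term outside the strict min/max bounds or before the retry clamp is
#' suppressed.
#'
#' @param start Current start date.
#' @param method Start method that produced it.
#' @param outcome_class,outcome_date Episode outcome.
#' @param events Categorized event table for the person.
#' @param config A [pregepi_config()].
#' @param floor_date Retry clamp floor (prior outcome + retry) or `NULL`.
#' @return List with `start_date` and `adjusted`.
#' @export
adjust_start <- function(start, method, outcome_class, outcome_date, events,
                         config = pregepi_config(), floor_date = NULL) {
  if (!method %in% c("amenorrhea", "urine_test", "outcome_estimate")) {
    return(list(start_date = start, adjusted = FALSE))
  }
  tw <- term_window_for(config, outcome_class)
  win_lo <- outcome_date - tw$max_term_days
  valid <- function(s) {
    term <- as.integer(outcome_date - s)
    term > tw$min_term_days && term < tw$max_term_days &&
      (is.null(floor_date) || s >= floor_date)
  }
  adjusted <- FALSE

  contra <- events$event_date[!is.na(events$category) &
                                events$category == "contraceptive" &
                                events$event_date >= win_lo &
                                events$event_date <= outcome_date]
  contra <- contra[contra > start & contra < outcome_date - tw$min_term_days]
  if (length(contra)) {
    cand <- max(contra) + 1L
    if (valid(cand)) {
      start <- cand
      adjusted <- TRUE
    }
  }

  conf <- events$event_date[!is.na(events$category) &
                              events$category == "preg_confirmation" &
                              events$event_date >= win_lo &
                              events$event_date <= outcome_date]
  if (length(conf)) {
    first_conf <- min(conf)
    if (first_conf < start) {
      cand <- first_conf - config$confirmation_lead_days
      if (valid(cand)) {
        start <- cand
        adjusted <- TRUE
      }
    }
  }

  list(start_date = start, adjusted = adjusted)
}
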