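# Step 1: outcome assessment and classification. Events of one person are
# walked in the fixed hierarchy order (live birth, stillbirth, ectopic,
# abortion, delivery-only) and, within a class, in date order; candidates
# are retained when they clear the inter-outcome spacing table, are not
# invalidated by antenatal follow-up, and (ectopic only) are confirmed by
# treatment or an ectopic-associated concept.

#' Inter-outcome spacing check
#'
#' A candidate outcome is independent of every already-accepted outcome when
#' the absolute day gap to each of them is at least the minimum required
#' duration configured for that ordered pair (earlier class, later class).
#' With `inclusive = TRUE` (default) a gap exactly equal to the table entry
#' passes.
#'
#' @param candidate_date Candidate record date (`Date`).
#' @param candidate_class Candidate outcome class.
#' @param accepted Data frame of this person's accepted outcomes with
#'   columns `outcome_class` and `final_date`; zero rows is vacuously true.
#' @param spacing 5x5 minimum-days matrix (see [pregepi_config()]).
#' @param inclusive Tie convention, see above.
#' @return `TRUE` when the candidate is far enough from all accepted
#'   outcomes.
#' @export
spacing_ok <- function(candidate_date, candidate_class, accepted, spacing,
                       inclusive = TRUE) {
  if (is.null(accepted) || nrow(accepted) == 0) return(TRUE)
  for (i in seq_len(nrow(accepted))) {
    acc_date <- accepted$final_date[i]
    acc_class <- accepted$outcome_class[i]
    if (candidate_date >= acc_date) {
      pair <- c(acc_class, candidate_class)
    } else {
      pair <- c(candidate_class, acc_class)
    }
    min_days <- spacing[pair[1], pair[2]]
    if (is.na(min_days)) {
      stop("spacing table has no entry for pair (", pair[1], ", ", pair[2], ")")
    }
    gap <- abs(as.integer(candidate_date - acc_date))
    ok <- if (inclusive) gap >= min_days else gap > min_days
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Follow-up invalidation check
#'
#' A candidate stillbirth/ectopic/abortion/delivery outcome does not become
#' an independent pregnancy episode when an antenatal visit or pregnancy
#' confirmation record falls in the window `(record, record + window_days]`
#' after the candidate record date: ongoing antenatal care contradicts the
#' putative end of the pregnancy (and screens out rule-out diagnoses).
#'
#' @param candidate_date Candidate record date.
#' @param events Categorized event table for the person.
#' @param window_days Window length; default 42.
#' @return `TRUE` when an invalidating record is present.
#' @export
invalidated_by_followup <- function(candidate_date, events, window_days = 42L) {
  dates <- events$event_date[!is.na(events$category) &
                               events$category %in% INVALIDATING_CATEGORIES]
  any(dates > candidate_date & dates <= candidate_date + window_days)
}

#' Ectopic confirmation and outcome-date reassignment
#'
#' An ectopic pregnancy record only stands when, during
#' `[record, record + confirm_window_days]`, the person has a methotrexate
#' exposure, an ectopic-related surgical procedure, or a concept curated as
#' highly associated with ectopic pregnancy. Day 0 is included: treatment is
#' commonly administered same-day in an emergency fashion. The outcome date
#' is reassigned to the last treatment date (methotrexate or surgery) in
#' that window; when confirmation rests only on an associated concept the
#' record date stands.
#'
#' @param record_date Ectopic record date.
#' @param events Categorized event table for the person.
#' @param confirm_window_days Window length; default 14.
#' @return List with `confirmed` (logical) and `final_date` (`Date`).
#' @export
confirm_and_date_ectopic <- function(record_date, events,
                                     confirm_window_days = 14L) {
  cat <- events$category
  in_win <- !is.na(cat) &
    events$event_date >= record_date &
    events$event_date <= record_date + confirm_window_days
  treat <- in_win & cat %in% c("methotrexate", "ectopic_surgery")
  assoc <- in_win & cat == "ectopic_associated"
  if (any(treat)) {
    list(confirmed = TRUE, final_date = max(events$event_date[treat]))
  } else if (any(assoc)) {
    list(confirmed = TRUE, final_date = record_date)
  } else {
    list(confirmed = FALSE, final_date = record_date)
  }
}

#' Abortion outcome-date reassignment
#'
#' The abortion outcome date is moved to the latest abortion-category record
#' in `[record, record + window_days]`, so that a cluster of abortion
#' billings ends the episode at the final procedure/diagnosis date.
#'
#' @param record_date Abortion record date.
#' @param events Categorized event table for the person.
#' @param window_days Window length; default 14.
#' @return The reassigned date (never earlier than `record_date`).
#' @export
reassign_abortion_date <- function(record_date, events, window_days = 14L) {
  dates <- events$event_date[!is.na(events$category) &
                               events$category == "abortion" &
                               events$event_date >= record_date &
                               events$event_date <= record_date + window_days]
  if (length(dates)) max(dates) else record_date
}

#' Classify pregnancy outcomes for one person
#'
#' Walks the person's categorized events through the outcome hierarchy
#' (live birth, stillbirth, ectopic, abortion, delivery-only), within each
#' class in date order; same-day duplicate records of one class collapse to
#' a single candidate. Each candidate is accepted iff it clears the spacing
#' table against all previously accepted outcomes, is not invalidated by an
#' antenatal-visit/pregnancy-confirmation follow-up (all classes but live
#' birth), and (ectopic) is confirmed by treatment or an associated concept.
#' Ectopic and abortion outcome dates are reassigned within their 14-day
#' windows; accepted delivery-only candidates are re-labelled live births.
#'
#' @param events Categorized event table for a single person.
#' @param config A [pregepi_config()].
#' @param all If `TRUE`, return every candidate with `accepted` and
#'   `rejection_reason` columns; default returns accepted outcomes only.
#' @return Data frame (`person_id`, `outcome_class`, `record_date`,
#'   `final_date`[, `accepted`, `rejection_reason`]); accepted outcomes are
#'   sorted by `final_date`.
#' @export
classify_outcomes <- function(events, config = pregepi_config(), all = FALSE) {
  pid <- unique(events$person_id)
  if (length(pid) > 1) stop("classify_outcomes processes one person at a time")
  if (length(pid) == 0) pid <- NA_character_

  cand_class <- character(0)
  cand_record <- cand_final <- as.Date(character(0))
  cand_ok <- logical(0)
  cand_reason <- character(0)

  acc_class <- character(0)
  acc_final <- as.Date(character(0))

  for (cls in OUTCOME_CLASSES) {
    dates <- sort(unique(events$event_date[!is.na(events$category) &
                                             events$category == cls]))
    for (d in seq_along(dates)) {
      rec <- dates[d]
      final <- rec
      ok <- TRUE
      reason <- "none"
      accepted_df <- data.frame(outcome_class = acc_class, final_date = acc_final,
                                stringsAsFactors = FALSE)
      if (!spacing_ok(rec, cls, accepted_df, config$spacing,
                      config$spacing_inclusive)) {
        ok <- FALSE
        reason <- "spacing"
      }
      if (ok && cls != "live_birth" &&
          invalidated_by_followup(rec, events, config$invalidation_window_days)) {
        ok <- FALSE
        reason <- "invalidated_by_followup"
      }
      if (ok && cls == "ectopic") {
        conf <- confirm_and_date_ectopic(rec, events,
                                         config$ectopic_confirm_window_days)
        if (!conf$confirmed) {
          ok <- FALSE
          reason <- "unconfirmed_ectopic"
        } else {
          final <- conf$final_date
        }
      }
      if (ok && cls == "abortion") {
        final <- reassign_abortion_date(rec, events, config$reassign_window_days)
      }
      if (ok) {
        acc_class <- c(acc_class, cls)
        acc_final <- c(acc_final, final)
      }
      cand_class <- c(cand_class, cls)
      cand_record <- c(cand_record, rec)
      cand_final <- c(cand_final, final)
      cand_ok <- c(cand_ok, ok)
      cand_reason <- c(cand_reason, reason)
    }
  }

  out <- data.frame(
    person_id = rep(pid, length(cand_class)),
    outcome_class = cand_class,
    record_date = cand_record,
    final_date = cand_final,
    accepted = cand_ok,
    rejection_reason = cand_reason,
    stringsAsFactors = FALSE
  )
  # delivery-only outcomes are live births once accepted
  out$outcome_class[out$accepted & out$outcome_class == "delivery"] <- "live_birth"
  if (!all) {
    out <- out[out$accepted, c("person_id", "outcome_class", "record_date",
                               "final_date")]
    out <- out[order(out$final_date, out$record_date), ]
    rownames(out) <- NULL
  }
  out
}
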