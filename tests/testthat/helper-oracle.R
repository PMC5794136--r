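# Independent, deliberately naive re-statement of the classification rules,
# used as a brute-force oracle. It rescans the full event table at every
# step with explicit loops and shares no code with the implementation.

oracle_classify <- function(events, config) {
  acc <- list()
  for (cls in c("live_birth", "stillbirth", "ectopic", "abortion", "delivery")) {
    dates <- c()
    for (i in seq_len(nrow(events))) {
      if (!is.na(events$category[i]) && events$category[i] == cls) {
        dates <- c(dates, events$event_date[i])
      }
    }
    dates <- sort(unique(as.Date(dates, origin = "1970-01-01")))
    for (rec in as.list(dates)) {
      ok <- TRUE
      # spacing against every accepted outcome
      for (a in acc) {
        gap <- abs(as.numeric(rec - a$final))
        if (rec >= a$final) {
          need <- config$spacing[a$cls, cls]
        } else {
          need <- config$spacing[cls, a$cls]
        }
        passed <- if (config$spacing_inclusive) gap >= need else gap > need
        if (!passed) ok <- FALSE
      }
      # follow-up invalidation (all classes except live birth)
      if (ok && cls != "live_birth") {
        for (i in seq_len(nrow(events))) {
          ci <- events$category[i]
          if (!is.na(ci) && (ci == "antenatal_visit" || ci == "preg_confirmation")) {
            off <- as.numeric(events$event_date[i] - rec)
            if (off > 0 && off <= config$invalidation_window_days) ok <- FALSE
          }
        }
      }
      final <- rec
      # ectopic confirmation and date reassignment
      if (ok && cls == "ectopic") {
        confirmed <- FALSE
        last_treat <- NULL
        for (i in seq_len(nrow(events))) {
          ci <- events$category[i]
          if (is.na(ci)) next
          off <- as.numeric(events$event_date[i] - rec)
          if (off >= 0 && off <= config$ectopic_confirm_window_days) {
            if (ci == "methotrexate" || ci == "ectopic_surgery") {
              confirmed <- TRUE
              if (is.null(last_treat) || events$event_date[i] > last_treat) {
                last_treat <- events$event_date[i]
              }
            } else if (ci == "ectopic_associated") {
              confirmed <- TRUE
            }
          }
        }
        if (!confirmed) ok <- FALSE
        if (confirmed && !is.null(last_treat)) final <- last_treat
      }
      # abortion date reassignment
      if (ok && cls == "abortion") {
        for (i in seq_len(nrow(events))) {
          ci <- events$category[i]
          if (!is.na(ci) && ci == "abortion") {
            off <- as.numeric(events$event_date[i] - rec)
            if (off >= 0 && off <= config$reassign_window_days &&
                events$event_date[i] > final) {
              final <- events$event_date[i]
            }
          }
        }
      }
      if (ok) acc[[length(acc) + 1]] <- list(cls = cls, final = final)
    }
  }
  if (!length(acc)) {
    return(data.frame(outcome_class = character(0),
                      final_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    outcome_class = vapply(acc, function(a) a$cls, ""),
    final_date = as.Date(vapply(acc, function(a) as.character(a$final), "")),
    stringsAsFactors = FALSE
  )
  out$outcome_class[out$outcome_class == "delivery"] <- "live_birth"
  out <- out[order(out$final_date, out$outcome_class), ]
  rownames(out) <- NULL
  out
}

# Interval oracle for marker term eligibility: strictly between the bounds.
oracle_marker_eligible <- function(gap_days, min_term, max_term) {
  gap_days > min_term && gap_days < max_term
}
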