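# Shared fixture builders. Dates are expressed as day offsets from a fixed
# origin so windows are easy to reason about in tests.

DAY0 <- as.Date("2010-01-01")

day <- function(n) DAY0 + n

# One categorized event row; the concept id encodes the category so a
# matching concept set can be derived with fixture_concept_set().
ev_row <- function(category, date, person_id = "P1", value = NA_real_,
                   unit = NA_character_) {
  data.frame(
    person_id = person_id,
    concept_id = paste0("FIX_", category),
    domain = "condition",
    event_date = if (inherits(date, "Date")) date else day(date),
    value = value, unit = unit, category = category,
    stringsAsFactors = FALSE
  )
}

ev_tbl <- function(...) {
  do.call(rbind, c(list(...), make.row.names = FALSE))
}

# A minimal single-person cohort around a prepared event table. Events are
# expected to already carry concept ids from the simulator vocabulary.
one_person_cohort <- function(events, sex = "female",
                              birth_date = as.Date("1985-06-15"),
                              period = c(day(-400), day(3000))) {
  structure(list(
    persons = data.frame(person_id = unique(events$person_id), sex = sex,
                         birth_date = birth_date, stringsAsFactors = FALSE),
    observation_periods = data.frame(person_id = unique(events$person_id),
                                     period_start = period[1],
                                     period_end = period[2],
                                     stringsAsFactors = FALSE),
    events = events[, c("person_id", "concept_id", "domain", "event_date",
                        "value", "unit")]
  ), class = "preg_cohort")
}

# Events built directly with categories, for use with a concept set that
# maps each fixture concept id to its category.
fixture_concept_set <- function(events) {
  pregepi:::as_concept_set(unique(data.frame(concept_id = events$concept_id,
                                             category = events$category,
                                             stringsAsFactors = FALSE)))
}

# Random classifier fixture: up to `max_candidates` outcome-class records
# plus supporting/confounding events, on a compressed 0..400-day axis so
# spacing, invalidation and confirmation windows all interact.
random_classifier_events <- function(max_candidates = 8L) {
  n_out <- sample(1:max_candidates, 1)
  cls <- sample(c("live_birth", "stillbirth", "ectopic", "abortion", "delivery"),
                n_out, replace = TRUE)
  dates <- sample(0:400, n_out, replace = TRUE)
  rows <- mapply(function(c, d) ev_row(c, d), cls, dates, SIMPLIFY = FALSE)
  n_extra <- sample(0:5, 1)
  if (n_extra) {
    extra_cls <- sample(c("antenatal_visit", "preg_confirmation", "methotrexate",
                          "ectopic_surgery", "ectopic_associated", "abortion"),
                        n_extra, replace = TRUE)
    extra_dates <- sample(0:430, n_extra, replace = TRUE)
    rows <- c(rows, mapply(function(c, d) ev_row(c, d), extra_cls, extra_dates,
                           SIMPLIFY = FALSE))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
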