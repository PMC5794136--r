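# Algorithm configuration: every temporal window the rule engine consults.

default_spacing_table <- function() {
  # Minimum days required between an earlier accepted outcome (rows) and a
  # later candidate outcome (columns) for both to stand as independent
  # pregnancies. These defaults are configuration, not published values:
  # the published supplementary table is not reproduced in the main text.
  # They are chosen so that (a) repeat billings of one delivery collapse,
  # (b) a later live birth must be at least a minimum gestation away from
  # any prior outcome, (c) rule-out abortion codes shortly before a birth
  # are rejected.
  cls <- OUTCOME_CLASSES
  m <- matrix(NA_integer_, 5, 5, dimnames = list(earlier = cls, later = cls))
  m["live_birth", ] <- c(182L, 168L, 70L, 56L, 182L)
  m["stillbirth", ] <- c(168L, 168L, 70L, 56L, 168L)
  m["ectopic", ]    <- c(168L, 126L, 56L, 56L, 168L)
  m["abortion", ]   <- c(168L, 126L, 56L, 56L, 168L)
  m["delivery", ]   <- c(182L, 168L, 70L, 56L, 182L)
  m
}

default_term_windows <- function() {
  # max_term_days: how far back from the outcome to search for markers
  # (301 for live births); min_term_days: shortest plausible gestation
  # (161 for live births); retry_days: days after an outcome before a new
  # pregnancy can begin. Live-birth min/max follow the published values;
  # the remaining rows are clinically plausible configuration.
  data.frame(
    outcome_class = EPISODE_CLASSES,
    min_term_days = c(161L, 140L, 28L, 28L),
    max_term_days = c(301L, 301L, 98L, 168L),
    retry_days    = c(28L, 28L, 14L, 14L),
    stringsAsFactors = FALSE
  )
}

default_hierarchy <- function() {
  # Ranked start-marker hierarchy, highest accuracy first. The implied
  # pregnancy start is marker date minus offset_days; gestational-age
  # records instead subtract the recorded gestational age (weeks x 7).
  data.frame(
    category = c("lmp", "gest_age", "fertility_dating", "nuchal_ultrasound",
                 "afp", "amenorrhea", "urine_test"),
    offset_days = c(0L, NA_integer_, 13L, 89L, 123L, 55L, 55L),
    method = c("lmp", "gest_age", "fertility", "nuchal_ultrasound", "afp",
               "amenorrhea", "urine_test"),
    stringsAsFactors = FALSE
  )
}

default_gestational_estimates <- function() {
  # Average gestational age (days) subtracted from the outcome date when no
  # start marker is eligible: full-term live birth 280, ectopic 56,
  # stillbirth 196, abortion 70. The preterm live-birth value (245) is
  # configuration; term status only changes the estimate for live births.
  m <- matrix(NA_integer_, 4, 2,
              dimnames = list(outcome_class = EPISODE_CLASSES,
                              term_status = c("full_term", "preterm")))
  m["live_birth", ] <- c(280L, 245L)
  m["stillbirth", ] <- c(196L, 196L)
  m["ectopic", ]    <- c(56L, 56L)
  m["abortion", ]   <- c(70L, 70L)
  m
}

#' Algorithm configuration
#'
#' Builds the full set of temporal windows and rule switches consumed by the
#' classifier, the start estimator and the pipeline. Every value can be
#' overridden by name; the result is validated before being returned.
#'
#' @param ... Named overrides for any configuration element, e.g.
#'   `spacing = my_matrix`, `invalidation_window_days = 42`.
#'
#' @details The elements are:
#' \describe{
#'   \item{spacing}{5x5 integer matrix of minimum days between an earlier
#'     accepted outcome (row) and a later candidate (column), over
#'     live_birth, stillbirth, ectopic, abortion, delivery.}
#'   \item{spacing_inclusive}{If `TRUE` (default) a gap exactly equal to the
#'     table entry still counts as independent; set `FALSE` for a strict
#'     comparison.}
#'   \item{invalidation_window_days}{A candidate stillbirth/ectopic/abortion/
#'     delivery is discarded when an antenatal visit or pregnancy
#'     confirmation falls in `(record, record + w]`; default 42.}
#'   \item{ectopic_confirm_window_days}{An ectopic outcome must be confirmed
#'     by methotrexate, ectopic surgery or an ectopic-associated concept in
#'     `[record, record + w]`; default 14 (day 0 included because treatment
#'     is commonly same-day and emergent).}
#'   \item{reassign_window_days}{Abortion (and ectopic treatment) outcome
#'     dates move to the latest qualifying event in `[record, record + w]`;
#'     default 14.}
#'   \item{term_windows}{Per-outcome `min_term_days`, `max_term_days`,
#'     `retry_days` (data frame).}
#'   \item{hierarchy}{Ranked marker categories with their day offsets.}
#'   \item{gestational_estimates}{Outcome x term-status fallback gestation
#'     lengths in days.}
#'   \item{confirmation_lead_days}{Days assumed between true start and the
#'     earliest pregnancy-confirmation record when adjusting low-confidence
#'     starts; default 28.}
#'   \item{min_markers}{Minimum categorized events inside the episode for
#'     inclusion; default 2.}
#'   \item{count_outcome_record}{Whether the outcome record itself counts
#'     toward `min_markers`; default `TRUE`.}
#'   \item{age_range}{Inclusive age bounds at episode start; default
#'     `c(12, 55)`.}
#'   \item{within_category_pick}{Which eligible event to use when one marker
#'     category has several: `"earliest"` (default) or `"latest"`.}
#' }
#'
#' @return A validated list of class `pregepi_config`.
#' @export
#' @examples
#' cfg <- pregepi_config(invalidation_window_days = 30)
#' cfg$term_windows
pregepi_config <- function(...) {
  cfg <- list(
    spacing = default_spacing_table(),
    spacing_inclusive = TRUE,
    invalidation_window_days = 42L,
    ectopic_confirm_window_days = 14L,
    reassign_window_days = 14L,
    term_windows = default_term_windows(),
    hierarchy = default_hierarchy(),
    gestational_estimates = default_gestational_estimates(),
    confirmation_lead_days = 28L,
    min_markers = 2L,
    count_outcome_record = TRUE,
    age_range = c(12L, 55L),
    within_category_pick = "earliest"
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration element(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  class(cfg) <- "pregepi_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  sp <- cfg$spacing
  if (!is.matrix(sp) || !identical(dim(sp), c(5L, 5L)) ||
      !setequal(rownames(sp), OUTCOME_CLASSES) ||
      !setequal(colnames(sp), OUTCOME_CLASSES)) {
    stop("spacing must be a 5x5 matrix over the outcome classes")
  }
  if (any(is.na(sp)) || any(sp <= 0)) stop("spacing entries must be positive")
  tw <- cfg$term_windows
  need <- c("outcome_class", "min_term_days", "max_term_days", "retry_days")
  if (!all(need %in% names(tw))) stop("term_windows missing columns")
  if (!setequal(tw$outcome_class, EPISODE_CLASSES)) {
    stop("term_windows must cover exactly the four episode classes")
  }
  if (any(tw$min_term_days <= 0) || any(tw$min_term_days >= tw$max_term_days)) {
    stop("term_windows require 0 < min_term_days < max_term_days")
  }
  if (any(tw$retry_days <= 0)) stop("retry_days must be positive")
  ge <- cfg$gestational_estimates
  for (cl in EPISODE_CLASSES) {
    lim <- tw[tw$outcome_class == cl, ]
    est <- ge[cl, ]
    if (any(est < lim$min_term_days | est > lim$max_term_days)) {
      stop("gestational estimate for ", cl, " outside its term window")
    }
  }
  hy <- cfg$hierarchy
  if (any(hy$offset_days < 0, na.rm = TRUE)) stop("hierarchy offsets must be >= 0")
  if (!cfg$within_category_pick %in% c("earliest", "latest")) {
    stop("within_category_pick must be 'earliest' or 'latest'")
  }
  invisible(cfg)
}

term_window_for <- function(cfg, outcome_class) {
  # delivery candidates are re-labelled live births before start estimation,
  # but be permissive if asked directly.
  if (outcome_class == "delivery") outcome_class <- "live_birth"
  row <- cfg$term_windows[cfg$term_windows$outcome_class == outcome_class, ]
  if (nrow(row) != 1) stop("no term window configured for class ", outcome_class)
  row
}

#' Write / read a configuration as JSON
#'
#' Serialises a `pregepi_config` to a JSON file so runs are reproducible and
#' window tables can be reviewed or edited outside R.
#'
#' @param cfg A `pregepi_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `pregepi_config`.
#' @export
write_config <- function(cfg, path) {
  out <- list(
    spacing = list(classes = rownames(cfg$spacing),
                   min_days = unclass(cfg$spacing)),
    spacing_inclusive = cfg$spacing_inclusive,
    invalidation_window_days = cfg$invalidation_window_days,
    ectopic_confirm_window_days = cfg$ectopic_confirm_window_days,
    reassign_window_days = cfg$reassign_window_days,
    term_windows = cfg$term_windows,
    hierarchy = cfg$hierarchy,
    gestational_estimates = list(classes = rownames(cfg$gestational_estimates),
                                 terms = colnames(cfg$gestational_estimates),
                                 days = unclass(cfg$gestational_estimates)),
    confirmation_lead_days = cfg$confirmation_lead_days,
    min_markers = cfg$min_markers,
    count_outcome_record = cfg$count_outcome_record,
    age_range = cfg$age_range,
    within_category_pick = cfg$within_category_pick
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- as.matrix(raw$spacing$min_days)
  dimnames(sp) <- list(earlier = raw$spacing$classes, later = raw$spacing$classes)
  ge <- as.matrix(raw$gestational_estimates$days)
  dimnames(ge) <- list(outcome_class = raw$gestational_estimates$classes,
                       term_status = raw$gestational_estimates$terms)
  pregepi_config(
    spacing = sp,
    spacing_inclusive = raw$spacing_inclusive,
    invalidation_window_days = as.integer(raw$invalidation_window_days),
    ectopic_confirm_window_days = as.integer(raw$ectopic_confirm_window_days),
    reassign_window_days = as.integer(raw$reassign_window_days),
    term_windows = as.data.frame(raw$term_windows),
    hierarchy = as.data.frame(raw$hierarchy),
    gestational_estimates = ge,
    confirmation_lead_days = as.integer(raw$confirmation_lead_days),
    min_markers = as.integer(raw$min_markers),
    count_outcome_record = raw$count_outcome_record,
    age_range = as.integer(raw$age_range),
    within_category_pick = raw$within_category_pick
  )
}
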