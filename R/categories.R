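# Category vocabulary shared by all stages.

# Categories used during outcome classification. `delivery` is transient
# (accepted deliveries are re-labelled live births); methotrexate,
# ectopic_surgery and ectopic_associated are confirmation evidence, not
# outcomes in their own right.
OUTCOME_CATEGORIES <- c(
  "live_birth", "stillbirth", "abortion", "delivery", "ectopic",
  "methotrexate", "ectopic_surgery", "ectopic_associated"
)

# Categories used during start estimation (and follow-up invalidation).
MARKER_CATEGORIES <- c(
  "preterm", "gest_age", "lmp", "preg_confirmation", "antenatal_visit",
  "complication", "threatened_abortion", "afp", "nuchal_ultrasound",
  "fertility_dating", "amenorrhea", "contraceptive", "urine_test"
)

# Outcome classes assessed, in fixed hierarchy order.
OUTCOME_CLASSES <- c("live_birth", "stillbirth", "ectopic", "abortion", "delivery")

# Final episode outcome classes (delivery has been re-labelled by then).
EPISODE_CLASSES <- c("live_birth", "stillbirth", "ectopic", "abortion")

START_METHODS <- c(
  "lmp", "gest_age", "fertility", "nuchal_ultrasound", "afp",
  "amenorrhea", "urine_test", "outcome_estimate"
)

# Events in these categories invalidate a candidate stillbirth / ectopic /
# abortion / delivery outcome when found shortly after the record date.
INVALIDATING_CATEGORIES <- c("antenatal_visit", "preg_confirmation")

#' Category vocabulary
#'
#' Returns the fixed category names recognised by the algorithm: the outcome
#' classification family and the start-marker family. The two families are
#' disjoint; concept sets must map every concept to exactly one of these
#' names.
#'
#' @return A named list with elements `outcome`, `marker`, `outcome_classes`
#'   (hierarchy order), `episode_classes` and `start_methods`.
#' @export
#' @examples
#' pregepi_categories()$outcome_classes
pregepi_categories <- function() {
  list(
    outcome = OUTCOME_CATEGORIES,
    marker = MARKER_CATEGORIES,
    outcome_classes = OUTCOME_CLASSES,
    episode_classes = EPISODE_CLASSES,
    start_methods = START_METHODS
  )
}
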