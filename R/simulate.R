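# Synthetic claims cohort generator. Plants pregnancies with known
# conception-anchor (day-0) and outcome dates, emits markers at their
# clinically scheduled gestational offsets, and optionally layers claims
# noise (repeat billings, rule-out abortion codes before preterm births,
# isolated historical outcome codes, marker dropout). Everything is
# reproducible from a single seed; per-person substreams make the first k
# persons identical regardless of n_persons.

SIM_CONCEPTS <- c(
  live_birth = "SIM_LB", stillbirth = "SIM_SB", abortion = "SIM_AB",
  delivery = "SIM_DEL", ectopic = "SIM_ECT", methotrexate = "SIM_MTX",
  ectopic_surgery = "SIM_ESURG", ectopic_associated = "SIM_EASSOC",
  preterm = "SIM_PRETERM", gest_age = "SIM_GEST", lmp = "SIM_LMP",
  preg_confirmation = "SIM_PCONF", antenatal_visit = "SIM_ANV",
  complication = "SIM_COMPL", threatened_abortion = "SIM_THREAT",
  afp = "SIM_AFP", nuchal_ultrasound = "SIM_ULS",
  fertility_dating = "SIM_FERT", amenorrhea = "SIM_AMEN",
  contraceptive = "SIM_CONTRA", urine_test = "SIM_URINE"
)

SIM_DOMAINS <- c(
  live_birth = "condition", stillbirth = "condition", abortion = "condition",
  delivery = "procedure", ectopic = "condition", methotrexate = "drug",
  ectopic_surgery = "procedure", ectopic_associated = "condition",
  preterm = "condition", gest_age = "observation", lmp = "observation",
  preg_confirmation = "condition", antenatal_visit = "observation",
  complication = "condition", threatened_abortion = "condition",
  afp = "procedure", nuchal_ultrasound = "procedure",
  fertility_dating = "procedure", amenorrhea = "condition",
  contraceptive = "drug", urine_test = "procedure"
)

#' Concept set used by the simulator
#'
#' One synthetic concept identifier per algorithm category (`SIM_LB`,
#' `SIM_ULS`, ...). Pipe simulator output through [categorize_events()]
#' with this set.
#'
#' @return A `concept_set` data frame.
#' @export
default_concept_sets <- function() {
  as_concept_set(data.frame(concept_id = unname(SIM_CONCEPTS),
                            category = names(SIM_CONCEPTS),
                            stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Declares the world the generator emits: cohort size and calendar,
#' outcome mix, term-length distributions, the gestational-day schedule on
#' which each marker category is recorded, and claims-noise rates (all zero
#' by default). Defaults mirror a US-claims-like population: outcome mix
#' roughly 73% live births / 25% abortions / 1.5% ectopic / 0.5%
#' stillbirths, live-birth terms normal(280, 10) truncated to the plausible
#' range, screening markers on their guideline days (nuchal 89, AFP 123,
#' amenorrhea-type contact 55).
#'
#' @param n_persons Number of persons.
#' @param seed Integer seed; the sole source of randomness.
#' @param ... Named overrides of any default element, notably:
#'   `epoch` (Date, default 2010-01-01), `obs_days` (observation span,
#'   default 1095), `age_range_at_epoch` (default `c(16, 42)`),
#'   `female_prob` (default 1), `outcome_probs`, `term_mean`, `term_sd`,
#'   `term_trunc`, `markers` (data frame `category`/`prob`/`gest_day`),
#'   `gest_week_range`, `antenatal_days`, `antenatal_prob`,
#'   `preterm_threshold`, `preterm_marker_prob`, `delivery_code_prob`,
#'   `second_pregnancy_prob`, `inter_pregnancy_gap`, `conception_window`,
#'   and `noise` (list `repeat_billing`, `rule_out_abortion`,
#'   `historical_code`, `marker_dropout`, all rates in \[0, 1\]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 100L, seed = 1L, ...) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    seed = as.integer(seed),
    epoch = as.Date("2010-01-01"),
    obs_days = 1095L,
    age_range_at_epoch = c(16, 42),
    female_prob = 1,
    outcome_probs = c(live_birth = 0.73, abortion = 0.25,
                      ectopic = 0.015, stillbirth = 0.005),
    term_mean = c(live_birth = 280, stillbirth = 196, ectopic = 56, abortion = 70),
    term_sd = c(live_birth = 10, stillbirth = 21, ectopic = 7, abortion = 14),
    term_trunc = list(live_birth = c(162L, 300L), stillbirth = c(141L, 300L),
                      ectopic = c(29L, 97L), abortion = c(29L, 167L)),
    markers = data.frame(
      category = c("lmp", "fertility_dating", "nuchal_ultrasound", "afp",
                   "amenorrhea", "urine_test", "preg_confirmation"),
      prob = c(0.25, 0.05, 0.5, 0.4, 0.3, 0.3, 0.8),
      gest_day = c(0L, 13L, 89L, 123L, 55L, 55L, 42L),
      stringsAsFactors = FALSE
    ),
    gest_age_prob = 0.2,
    gest_week_range = c(8L, 20L),
    antenatal_days = c(84L, 168L, 252L),
    antenatal_prob = 0.8,
    preterm_threshold = 259L,
    preterm_marker_prob = 0.9,
    delivery_code_prob = 0.5,
    second_pregnancy_prob = 0.15,
    inter_pregnancy_gap = c(90L, 250L),
    conception_window = c(30L, 365L),
    noise = list(repeat_billing = 0, rule_out_abortion = 0,
                 historical_code = 0, marker_dropout = 0)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown sim_config element(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  if (cfg$n_persons < 0) stop("n_persons must be >= 0")
  probs <- c(cfg$outcome_probs, cfg$markers$prob, cfg$female_prob,
             cfg$antenatal_prob, cfg$preterm_marker_prob,
             cfg$delivery_code_prob, cfg$second_pregnancy_prob,
             cfg$gest_age_prob, unlist(cfg$noise))
  if (any(probs < 0 | probs > 1)) stop("all probabilities/rates must be in [0, 1]")
  if (abs(sum(cfg$outcome_probs) - 1) > 1e-8) stop("outcome_probs must sum to 1")
  for (cl in names(cfg$term_trunc)) {
    tr <- cfg$term_trunc[[cl]]
    if (tr[1] >= tr[2]) stop("term truncation bounds must be increasing for ", cl)
  }
  class(cfg) <- "sim_config"
  cfg
}

draw_term <- function(cls, cfg) {
  tr <- cfg$term_trunc[[cls]]
  for (k in 1:200) {
    t <- as.integer(round(stats::rnorm(1, cfg$term_mean[[cls]], cfg$term_sd[[cls]])))
    if (t >= tr[1] && t <= tr[2]) return(t)
  }
  as.integer(round(cfg$term_mean[[cls]]))
}

sim_event <- function(pid, category, date, value = NA_real_, unit = NA_character_) {
  list(person_id = pid, concept_id = unname(SIM_CONCEPTS[[category]]),
       domain = unname(SIM_DOMAINS[[category]]), event_date = date,
       value = value, unit = unit)
}

emit_episode <- function(pid, start_date, cls, term, cfg) {
  ev <- list()
  markers <- character(0)
  outcome_date <- start_date + term

  # outcome records
  ev[[length(ev) + 1]] <- sim_event(pid, cls, outcome_date)
  if (cls == "live_birth" && stats::runif(1) < cfg$delivery_code_prob) {
    ev[[length(ev) + 1]] <- sim_event(pid, "delivery", outcome_date)
  }
  if (cls == "ectopic") {
    # same-day emergency treatment confirms the diagnosis
    ev[[length(ev) + 1]] <- sim_event(pid, "methotrexate", outcome_date)
  }

  # scheduled start markers, only while the pregnancy is ongoing
  for (r in seq_len(nrow(cfg$markers))) {
    day <- cfg$markers$gest_day[r]
    if (day >= term && day != 0L) next
    if (stats::runif(1) < cfg$markers$prob[r]) {
      cat <- cfg$markers$category[r]
      ev[[length(ev) + 1]] <- sim_event(pid, cat, start_date + day)
      markers <- c(markers, cat)
    }
  }
  # gestational-age record: value in weeks, dated at that gestational week
  if (stats::runif(1) < cfg$gest_age_prob) {
    wmax <- min(cfg$gest_week_range[2], (term - 1L) %/% 7L)
    if (wmax >= cfg$gest_week_range[1]) {
      w <- if (wmax == cfg$gest_week_range[1]) wmax else
        sample(cfg$gest_week_range[1]:wmax, 1)
      ev[[length(ev) + 1]] <- sim_event(pid, "gest_age", start_date + w * 7L,
                                        value = w, unit = "weeks")
      markers <- c(markers, "gest_age")
    }
  }
  # antenatal contacts
  for (day in cfg$antenatal_days) {
    if (day < term && stats::runif(1) < cfg$antenatal_prob) {
      ev[[length(ev) + 1]] <- sim_event(pid, "antenatal_visit", start_date + day)
      markers <- c(markers, "antenatal_visit")
    }
  }
  # preterm marker for early live births
  if (cls == "live_birth" && term < cfg$preterm_threshold &&
      stats::runif(1) < cfg$preterm_marker_prob) {
    ev[[length(ev) + 1]] <- sim_event(pid, "preterm", outcome_date)
    markers <- c(markers, "preterm")
  }
  list(events = ev, markers = markers, outcome_date = outcome_date)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Simulates persons, observation periods (one per person, `obs_days` long
#' from `epoch`), clinical events and a ground-truth table of planted
#' pregnancy episodes. With all noise rates zero, every emitted marker sits
#' exactly on its configured gestational day, so the algorithm can recover
#' planted starts exactly via day-anchored markers. Calling
#' [inject_noise()] is automatic when any noise rate is positive.
#'
#' @param cfg A [sim_config()].
#' @return A `preg_cohort` list (`persons`, `observation_periods`,
#'   `events`, `ground_truth`); `ground_truth` has one row per planted
#'   episode (`person_id`, `episode`, `true_outcome_class`,
#'   `true_start_date`, `true_outcome_date`, `markers`).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_persons
  set.seed(cfg$seed)
  person_seeds <- if (n > 0) sample.int(2147483646L, n) else integer(0)

  persons <- vector("list", n)
  gt <- list()
  ev <- list()

  for (i in seq_len(n)) {
    set.seed(person_seeds[i])
    pid <- sprintf("P%05d", i)
    female <- stats::runif(1) < cfg$female_prob
    age0 <- stats::runif(1, cfg$age_range_at_epoch[1], cfg$age_range_at_epoch[2])
    birth <- cfg$epoch - as.integer(round(age0 * 365.25))
    persons[[i]] <- list(person_id = pid,
                         sex = if (female) "female" else "male",
                         birth_date = birth)
    if (!female) next

    c1 <- sample(cfg$conception_window[1]:cfg$conception_window[2], 1)
    cls1 <- sample(names(cfg$outcome_probs), 1, prob = cfg$outcome_probs)
    term1 <- draw_term(cls1, cfg)
    ep1 <- emit_episode(pid, cfg$epoch + c1, cls1, term1, cfg)
    ev <- c(ev, ep1$events)
    gt[[length(gt) + 1]] <- list(
      person_id = pid, episode = 1L, true_outcome_class = cls1,
      true_start_date = cfg$epoch + c1, true_outcome_date = ep1$outcome_date,
      markers = paste(sort(unique(ep1$markers)), collapse = ";")
    )

    if (stats::runif(1) < cfg$second_pregnancy_prob) {
      gap <- sample(cfg$inter_pregnancy_gap[1]:cfg$inter_pregnancy_gap[2], 1)
      c2 <- c1 + term1 + gap
      cls2 <- sample(names(cfg$outcome_probs), 1, prob = cfg$outcome_probs)
      term2 <- draw_term(cls2, cfg)
      if (c2 + term2 <= cfg$obs_days - 14L) {
        ep2 <- emit_episode(pid, cfg$epoch + c2, cls2, term2, cfg)
        ev <- c(ev, ep2$events)
        gt[[length(gt) + 1]] <- list(
          person_id = pid, episode = 2L, true_outcome_class = cls2,
          true_start_date = cfg$epoch + c2, true_outcome_date = ep2$outcome_date,
          markers = paste(sort(unique(ep2$markers)), collapse = ";")
        )
      }
    }
  }

  persons_df <- if (n > 0) {
    data.frame(person_id = vapply(persons, `[[`, "", "person_id"),
               sex = vapply(persons, `[[`, "", "sex"),
               birth_date = as.Date(vapply(persons, function(p)
                 as.character(p$birth_date), "")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(person_id = character(0), sex = character(0),
               birth_date = as.Date(character(0)), stringsAsFactors = FALSE)
  }
  periods_df <- data.frame(
    person_id = persons_df$person_id,
    period_start = rep(cfg$epoch, nrow(persons_df)),
    period_end = rep(cfg$epoch + cfg$obs_days, nrow(persons_df)),
    stringsAsFactors = FALSE
  )
  events_df <- bind_event_list(ev)
  gt_df <- if (length(gt)) {
    data.frame(person_id = vapply(gt, `[[`, "", "person_id"),
               episode = vapply(gt, `[[`, 0L, "episode"),
               true_outcome_class = vapply(gt, `[[`, "", "true_outcome_class"),
               true_start_date = as.Date(vapply(gt, function(g)
                 as.character(g$true_start_date), "")),
               true_outcome_date = as.Date(vapply(gt, function(g)
                 as.character(g$true_outcome_date), "")),
               markers = vapply(gt, `[[`, "", "markers"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(person_id = character(0), episode = integer(0),
               true_outcome_class = character(0),
               true_start_date = as.Date(character(0)),
               true_outcome_date = as.Date(character(0)),
               markers = character(0), stringsAsFactors = FALSE)
  }

  cohort <- list(persons = persons_df, observation_periods = periods_df,
                 events = events_df, ground_truth = gt_df)
  class(cohort) <- "preg_cohort"
  if (any(unlist(cfg$noise) > 0)) {
    cohort$events <- inject_noise(cohort$events, gt_df, cfg)
  }
  cohort
}

bind_event_list <- function(ev) {
  if (!length(ev)) return(empty_events())
  df <- data.frame(
    person_id = vapply(ev, `[[`, "", "person_id"),
    concept_id = vapply(ev, `[[`, "", "concept_id"),
    domain = vapply(ev, `[[`, "", "domain"),
    event_date = as.Date(vapply(ev, function(e) as.character(e$event_date), "")),
    value = vapply(ev, `[[`, 0, "value"),
    unit = vapply(ev, `[[`, "", "unit"),
    stringsAsFactors = FALSE
  )
  df[order(df$person_id, df$event_date, df$concept_id), , drop = FALSE]
}

#' Inject claims noise into simulated events
#'
#' Adds, per the configured rates: duplicate outcome billings 1-7 days
#' after each planted outcome (`repeat_billing`); a rule-out abortion code
#' 0-30 days before planted preterm live births (`rule_out_abortion`); an
#' isolated historical live-birth code late in the observation period for
#' persons with a single planted episode (`historical_code`), placed only
#' where its backward search window is free of planted events; and removal
#' of marker-category events (`marker_dropout`). Seeded deterministically
#' from the simulation seed.
#'
#' @param events Simulated event table.
#' @param ground_truth Ground-truth table from [generate_cohort()].
#' @param cfg The [sim_config()].
#' @return The event table with noise rows added/removed, re-sorted.
#' @export
inject_noise <- function(events, ground_truth, cfg) {
  nz <- cfg$noise
  set.seed((cfg$seed %% 2000000000L) + 104729L)
  add <- list()

  if (nrow(ground_truth)) {
    for (i in seq_len(nrow(ground_truth))) {
      g <- ground_truth[i, ]
      if (nz$repeat_billing > 0 && stats::runif(1) < nz$repeat_billing) {
        add[[length(add) + 1]] <- sim_event(
          g$person_id, g$true_outcome_class,
          g$true_outcome_date + sample(1:7, 1)
        )
      }
      term <- as.integer(g$true_outcome_date - g$true_start_date)
      if (nz$rule_out_abortion > 0 && g$true_outcome_class == "live_birth" &&
          term < cfg$preterm_threshold &&
          stats::runif(1) < nz$rule_out_abortion) {
        add[[length(add) + 1]] <- sim_event(
          g$person_id, "abortion", g$true_outcome_date - sample(0:30, 1)
        )
      }
    }
    if (nz$historical_code > 0) {
      tab <- table(ground_truth$person_id)
      singles <- names(tab)[tab == 1]
      for (pid in singles) {
        g <- ground_truth[ground_truth$person_id == pid, ]
        hist_date <- cfg$epoch + cfg$obs_days - 45L
        # keep the historical code's whole search window clear of the episode
        if (hist_date - 301L > g$true_outcome_date &&
            stats::runif(1) < nz$historical_code) {
          add[[length(add) + 1]] <- sim_event(pid, "live_birth", hist_date)
        }
      }
    }
  }

  if (nz$marker_dropout > 0 && nrow(events)) {
    cs <- default_concept_sets()
    cat <- cs$category[match(events$concept_id, cs$concept_id)]
    is_marker <- !is.na(cat) & cat %in% MARKER_CATEGORIES
    drop <- is_marker & stats::runif(nrow(events)) < nz$marker_dropout
    events <- events[!drop, , drop = FALSE]
  }

  if (length(add)) {
    events <- rbind(events, bind_event_list(add))
  }
  events <- events[order(events$person_id, events$event_date, events$concept_id), ,
                   drop = FALSE]
  rownames(events) <- NULL
  events
}
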