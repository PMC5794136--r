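# Characterization and validation analytics over an episode set.

METHOD_GROUPS <- c(
  lmp = "group1", gest_age = "group1", fertility = "group1",
  afp = "group2", nuchal_ultrasound = "group2",
  amenorrhea = "group3", urine_test = "group3",
  outcome_estimate = "group4"
)

#' Characterize an episode set
#'
#' Produces the standard descriptive tables: outcome-class proportions; the
#' distribution of start estimation method per outcome, with the four-way
#' method grouping (group 1 = LMP / gestational age / fertility procedure,
#' group 2 = AFP / nuchal ultrasound, group 3 = amenorrhea / urine test,
#' group 4 = average gestational-age estimate); and pregnancy duration
#' summaries — counts in 10-day bins (a duration of 275 falls in bin
#' 270-279) and the median duration per start method and outcome.
#' Percentages are unrounded proportions times 100 and sum to 100 within
#' each stratum.
#'
#' @param episodes Episode data frame from [build_episodes()].
#' @return List of data frames: `outcome_proportions`, `start_methods`,
#'   `method_groups`, `duration_bins`, `duration_medians`. Empty input
#'   yields empty tables with headers.
#' @export
characterize <- function(episodes) {
  if (nrow(episodes) == 0) {
    return(list(
      outcome_proportions = data.frame(outcome_class = character(0),
                                       n = integer(0), pct = numeric(0)),
      start_methods = data.frame(outcome_class = character(0),
                                 start_method = character(0),
                                 n = integer(0), pct = numeric(0)),
      method_groups = data.frame(outcome_class = character(0),
                                 method_group = character(0),
                                 n = integer(0), pct = numeric(0)),
      duration_bins = data.frame(start_method = character(0),
                                 bin = character(0), bin_lower = integer(0),
                                 n = integer(0), pct = numeric(0)),
      duration_medians = data.frame(outcome_class = character(0),
                                    start_method = character(0),
                                    n = integer(0), median_days = numeric(0))
    ))
  }
  n_total <- nrow(episodes)
  tab <- table(episodes$outcome_class)
  outcome_proportions <- data.frame(
    outcome_class = names(tab), n = as.integer(tab),
    pct = 100 * as.integer(tab) / n_total, stringsAsFactors = FALSE
  )

  per_stratum <- function(f) {
    agg <- stats::aggregate(list(n = seq_len(n_total)),
                            by = f, FUN = length)
    agg
  }
  sm <- per_stratum(list(outcome_class = episodes$outcome_class,
                         start_method = episodes$start_method))
  totals <- tapply(sm$n, sm$outcome_class, sum)
  sm$pct <- 100 * sm$n / as.numeric(totals[sm$outcome_class])
  sm <- sm[order(sm$outcome_class, sm$start_method), ]
  rownames(sm) <- NULL

  grp <- unname(METHOD_GROUPS[episodes$start_method])
  mg <- per_stratum(list(outcome_class = episodes$outcome_class,
                         method_group = grp))
  mg$pct <- 100 * mg$n / as.numeric(totals[mg$outcome_class])
  mg <- mg[order(mg$outcome_class, mg$method_group), ]
  rownames(mg) <- NULL

  dur <- as.integer(episodes$outcome_date - episodes$start_date)
  lower <- (dur %/% 10L) * 10L
  db <- per_stratum(list(start_method = episodes$start_method,
                         bin_lower = lower))
  mtot <- tapply(db$n, db$start_method, sum)
  db$pct <- 100 * db$n / as.numeric(mtot[db$start_method])
  db$bin <- sprintf("%d-%d", db$bin_lower, db$bin_lower + 9L)
  db <- db[order(db$start_method, db$bin_lower),
           c("start_method", "bin", "bin_lower", "n", "pct")]
  rownames(db) <- NULL

  dm <- stats::aggregate(list(median_days = dur),
                         by = list(outcome_class = episodes$outcome_class,
                                   start_method = episodes$start_method),
                         FUN = stats::median)
  dmn <- stats::aggregate(list(n = dur),
                          by = list(outcome_class = episodes$outcome_class,
                                    start_method = episodes$start_method),
                          FUN = length)
  dm <- merge(dmn, dm, by = c("outcome_class", "start_method"))
  dm <- dm[order(dm$outcome_class, dm$start_method), ]
  rownames(dm) <- NULL

  list(outcome_proportions = outcome_proportions, start_methods = sm,
       method_groups = mg, duration_bins = db, duration_medians = dm)
}

episode_prior <- function(episodes, i) {
  # the included episode immediately before episode i for the same person
  pid <- episodes$person_id[i]
  prev <- episodes[episodes$person_id == pid &
                     episodes$outcome_date < episodes$outcome_date[i], ]
  if (!nrow(prev)) return(NULL)
  j <- which.max(as.integer(prev$outcome_date))
  list(outcome_class = prev$outcome_class[j], final_date = prev$outcome_date[j])
}

#' Fertility-procedure start sensitivity analysis
#'
#' For every episode that has an eligible conception-dating fertility
#' procedure, compares the fertility-based start (procedure date minus its
#' offset) against the start the algorithm would pick with all fertility
#' markers masked (the next-highest eligible marker, or the average
#' estimate). Absolute differences are binned into <=7, 8-14 and >14 days,
#' reported per outcome class.
#'
#' @param episodes Episode data frame.
#' @param events Categorized event table for the cohort.
#' @param config A [pregepi_config()].
#' @return Data frame (`outcome_class`, `bin`, `n`, `pct`); zero rows when
#'   no episode carries a fertility marker. Within each outcome the bins
#'   partition the episodes, so counts sum to the episode count.
#' @export
fertility_sensitivity <- function(episodes, events, config = pregepi_config()) {
  bins <- c("<=7", "8-14", ">14")
  if (!"category" %in% names(events)) {
    stop("events must be categorized first (see categorize_events)")
  }
  recs <- list()
  offset <- config$hierarchy$offset_days[config$hierarchy$category == "fertility_dating"]
  for (i in seq_len(nrow(episodes))) {
    pid <- episodes$person_id[i]
    pe <- events[events$person_id == pid & !is.na(events$category), , drop = FALSE]
    prior <- episode_prior(episodes, i)
    el <- eligible_markers(episodes$outcome_class[i], episodes$outcome_date[i],
                           pe, config, prior)
    fert <- el[el$category == "fertility_dating", , drop = FALSE]
    if (!nrow(fert)) next
    start_fert <- min(fert$event_date) - offset
    masked <- pe[pe$category != "fertility_dating", , drop = FALSE]
    alt <- estimate_start(episodes$outcome_class[i], episodes$outcome_date[i],
                          masked, config, prior)
    d <- abs(as.integer(alt$start_date - start_fert))
    bin <- if (d <= 7) "<=7" else if (d <= 14) "8-14" else ">14"
    recs[[length(recs) + 1]] <- data.frame(
      outcome_class = episodes$outcome_class[i], bin = bin,
      alt_method = alt$start_method, diff_days = d, stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) {
    return(data.frame(outcome_class = character(0), bin = character(0),
                      n = integer(0), pct = numeric(0)))
  }
  df <- do.call(rbind, recs)
  out <- list()
  for (cls in sort(unique(df$outcome_class))) {
    sub <- df[df$outcome_class == cls, ]
    n <- vapply(bins, function(b) sum(sub$bin == b), 0L)
    out[[cls]] <- data.frame(outcome_class = cls, bin = bins, n = n,
                             pct = 100 * n / nrow(sub), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res
}

#' Marker proximity to an anchor-implied start
#'
#' Among episodes that carry an eligible anchor marker (a conception-dating
#' fertility procedure or a nuchal ultrasound), computes per marker
#' category the percentage of eligible markers whose implied start falls
#' within 14 days before or after the anchor-implied start. This is the
#' analysis used to order the lower ranks of the start hierarchy.
#'
#' @param episodes Episode data frame.
#' @param events Categorized event table.
#' @param anchor_category `"fertility_dating"` or `"nuchal_ultrasound"`.
#' @param config A [pregepi_config()].
#' @return Data frame (`category`, `n_markers`, `n_within`, `pct_within`);
#'   zero rows when no episode has the anchor.
#' @export
marker_proximity <- function(episodes, events, anchor_category,
                             config = pregepi_config()) {
  stopifnot(anchor_category %in% c("fertility_dating", "nuchal_ultrasound"))
  if (!"category" %in% names(events)) {
    stop("events must be categorized first (see categorize_events)")
  }
  tally <- list()
  for (i in seq_len(nrow(episodes))) {
    pid <- episodes$person_id[i]
    pe <- events[events$person_id == pid & !is.na(events$category), , drop = FALSE]
    prior <- episode_prior(episodes, i)
    el <- eligible_markers(episodes$outcome_class[i], episodes$outcome_date[i],
                           pe, config, prior)
    anchor <- el[el$category == anchor_category, , drop = FALSE]
    if (!nrow(anchor)) next
    anchor_start <- anchor$implied_start[which.min(anchor$event_date)]
    others <- el[el$category != anchor_category, , drop = FALSE]
    if (!nrow(others)) next
    others$within <- abs(as.integer(others$implied_start - anchor_start)) <= 14L
    tally[[length(tally) + 1]] <- others[, c("category", "within")]
  }
  if (!length(tally)) {
    return(data.frame(category = character(0), n_markers = integer(0),
                      n_within = integer(0), pct_within = numeric(0)))
  }
  df <- do.call(rbind, tally)
  cats <- sort(unique(df$category))
  out <- data.frame(
    category = cats,
    n_markers = vapply(cats, function(c) sum(df$category == c), 0L),
    n_within = vapply(cats, function(c) sum(df$within[df$category == c]), 0L),
    stringsAsFactors = FALSE
  )
  out$pct_within <- 100 * out$n_within / out$n_markers
  rownames(out) <- NULL
  out
}

#' Export plain-text review profiles
#'
#' Writes one text file per sampled episode for manual adjudication: a
#' header with the person, outcome class and dates, start method, and all
#' candidate starts the hierarchy identified, followed by every event of
#' the person ordered by time, each with its offset in days from the
#' inferred start. Sampling is seeded and stratified by outcome class
#' (up to `per_outcome` episodes per class; all of them when fewer exist).
#'
#' @param episodes Episode data frame.
#' @param events Categorized event table.
#' @param out_dir Output directory.
#' @param per_outcome Episodes to sample per outcome class; default 50.
#' @param seed Sampling seed.
#' @param config A [pregepi_config()].
#' @return Character vector of files written, invisibly.
#' @export
export_profiles <- function(episodes, events, out_dir, per_outcome = 50L,
                            seed = 1L, config = pregepi_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  for (cls in sort(unique(episodes$outcome_class))) {
    idx <- which(episodes$outcome_class == cls)
    take <- if (length(idx) > per_outcome) sort(sample(idx, per_outcome)) else idx
    for (i in take) {
      pid <- episodes$person_id[i]
      pe <- events[events$person_id == pid, , drop = FALSE]
      pe <- pe[order(pe$event_date), , drop = FALSE]
      prior <- episode_prior(episodes, i)
      el <- eligible_markers(cls, episodes$outcome_date[i],
                             pe[!is.na(pe$category), , drop = FALSE],
                             config, prior)
      cand <- if (nrow(el)) {
        paste(sprintf("%s=%s", el$method, fmt_date(el$implied_start)),
              collapse = " ")
      } else "(none)"
      start <- episodes$start_date[i]
      lines <- c(
        sprintf("person: %s  episode: %d", pid, episodes$episode_index[i]),
        sprintf("outcome_class: %s  outcome_date: %s", cls,
                fmt_date(episodes$outcome_date[i])),
        sprintf("start_date: %s  start_method: %s", fmt_date(start),
                episodes$start_method[i]),
        sprintf("candidate_starts: %s", cand),
        "",
        "day\tdate\tdomain\tconcept_id\tcategory"
      )
      cat_col <- if ("category" %in% names(pe)) pe$category else rep(NA, nrow(pe))
      lines <- c(lines, sprintf(
        "%d\t%s\t%s\t%s\t%s",
        as.integer(pe$event_date - start), fmt_date(pe$event_date),
        pe$domain, pe$concept_id,
        ifelse(is.na(cat_col), "-", cat_col)
      ))
      f <- file.path(out_dir, sprintf("%s_ep%d.txt", pid, episodes$episode_index[i]))
      writeLines(lines, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
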