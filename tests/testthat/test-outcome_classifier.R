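cfg <- pregepi_config()

test_that("spacing_ok honours the pair table, boundary and tie convention", {
  acc <- data.frame(outcome_class = "live_birth", final_date = day(0),
                    stringsAsFactors = FALSE)
  sp <- cfg$spacing

  # vacuous with no accepted outcomes
  expect_true(spacing_ok(day(10), "live_birth",
                         acc[0, ], sp))

  # two live-birth records 1 day apart with min 182
  expect_false(spacing_ok(day(1), "live_birth", acc, sp))

  # gap exactly equal to the table entry passes (inclusive convention) ...
  expect_true(spacing_ok(day(182), "live_birth", acc, sp))
  expect_false(spacing_ok(day(181), "live_birth", acc, sp))
  # ... and fails under the strict switch
  expect_false(spacing_ok(day(182), "live_birth", acc, sp, inclusive = FALSE))
  expect_true(spacing_ok(day(183), "live_birth", acc, sp, inclusive = FALSE))

  # candidate before the accepted outcome uses the (candidate, accepted) pair:
  # an earlier abortion must be a full minimum gestation before the live birth
  expect_false(spacing_ok(day(-100), "abortion", acc, sp)) # gap 100 < 168
  expect_true(spacing_ok(day(-168), "abortion", acc, sp))
  # a later abortion only needs the (live_birth, abortion) entry of 56
  expect_true(spacing_ok(day(56), "abortion", acc, sp))

  # missing entry is a configuration error naming the pair
  sp2 <- sp; sp2["live_birth", "abortion"] <- NA
  expect_error(spacing_ok(day(300), "abortion", acc, sp2),
               "live_birth, abortion")
})

test_that("follow-up invalidation window is (record, record + 42]", {
  base <- ev_tbl(ev_row("stillbirth", 0))
  expect_false(invalidated_by_followup(day(0), base))
  got <- vapply(1:100, function(k) {
    ev <- rbind(base, ev_row("preg_confirmation", k))
    invalidated_by_followup(day(0), ev, 42L)
  }, logical(1))
  expect_equal(got, 1:100 <= 42)
  # same-day follow-up does not invalidate (day 0 excluded)
  ev0 <- rbind(base, ev_row("antenatal_visit", 0))
  expect_false(invalidated_by_followup(day(0), ev0, 42L))
})

test_that("ectopic confirmation window is [record, record + 14] with treatment-date reassignment", {
  base <- ev_tbl(ev_row("ectopic", 0))

  # methotrexate k days after the record; boundary at 14, day 0 included
  got <- lapply(0:60, function(k) {
    ev <- rbind(base, ev_row("methotrexate", k))
    confirm_and_date_ectopic(day(0), ev, 14L)
  })
  expect_equal(vapply(got, `[[`, TRUE, "confirmed"), 0:60 <= 14)
  expect_equal(got[[11]]$final_date, day(10))  # reassigned to the treatment date
  expect_equal(got[[16]]$final_date, day(0))   # 15 days: unconfirmed, date stands

  # no qualifying events
  expect_false(confirm_and_date_ectopic(day(0), base)$confirmed)

  # associated concept confirms but does not move the date
  ev <- rbind(base, ev_row("ectopic_associated", 5))
  res <- confirm_and_date_ectopic(day(0), ev)
  expect_true(res$confirmed)
  expect_equal(res$final_date, day(0))

  # last treatment in the window wins
  ev <- rbind(base, ev_row("methotrexate", 2), ev_row("ectopic_surgery", 9))
  expect_equal(confirm_and_date_ectopic(day(0), ev)$final_date, day(9))
})

test_that("abortion dates reassign to the last abortion record within 14 days", {
  ev <- ev_tbl(ev_row("abortion", 0), ev_row("abortion", 3), ev_row("abortion", 9))
  expect_equal(reassign_abortion_date(day(0), ev), day(9))
  expect_equal(reassign_abortion_date(day(0), ev_tbl(ev_row("abortion", 0))), day(0))
  ev2 <- ev_tbl(ev_row("abortion", 0), ev_row("abortion", 20))
  expect_equal(reassign_abortion_date(day(0), ev2), day(0))
})

test_that("classify_outcomes walks the hierarchy with spacing, invalidation and relabeling", {
  # one live-birth record -> one outcome at that date
  out <- classify_outcomes(ev_tbl(ev_row("live_birth", 100)), cfg)
  expect_equal(out$outcome_class, "live_birth")
  expect_equal(out$final_date, day(100))

  # LB at D and abortion at D+10: abortion rejected on spacing (needs 56)
  out <- classify_outcomes(
    ev_tbl(ev_row("live_birth", 100), ev_row("abortion", 110)), cfg, all = TRUE)
  ab <- out[out$outcome_class == "abortion", ]
  expect_false(ab$accepted)
  expect_equal(ab$rejection_reason, "spacing")

  # delivery-only record, no invalidating follow-up -> re-labeled live birth
  out <- classify_outcomes(ev_tbl(ev_row("delivery", 50)), cfg)
  expect_equal(out$outcome_class, "live_birth")

  # delivery with antenatal follow-up at +30 -> invalidated
  out <- classify_outcomes(
    ev_tbl(ev_row("delivery", 50), ev_row("antenatal_visit", 80)), cfg)
  expect_equal(nrow(out), 0)

  # live births are never invalidated by follow-up
  out <- classify_outcomes(
    ev_tbl(ev_row("live_birth", 50), ev_row("preg_confirmation", 60)), cfg)
  expect_equal(out$outcome_class, "live_birth")

  # same-day duplicate billings collapse to one candidate
  out <- classify_outcomes(
    ev_tbl(ev_row("live_birth", 50), ev_row("live_birth", 50)), cfg, all = TRUE)
  expect_equal(nrow(out), 1)

  # repeat billing 3 days later is rejected, not a second episode
  out <- classify_outcomes(
    ev_tbl(ev_row("live_birth", 50), ev_row("live_birth", 53)), cfg)
  expect_equal(nrow(out), 1)
})

test_that("classify_outcomes equals the brute-force oracle on random fixtures", {
  set.seed(2024)
  for (case in 1:400) {
    ev <- random_classifier_events()
    got <- classify_outcomes(ev, cfg)[, c("outcome_class", "final_date")]
    want <- oracle_classify(ev, cfg)
    key <- function(d) d[order(d$final_date, d$outcome_class), , drop = FALSE]
    got <- key(got); rownames(got) <- NULL
    want <- key(want); rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("accepted outcomes always respect the spacing table", {
  set.seed(99)
  for (case in 1:100) {
    ev <- random_classifier_events()
    out <- classify_outcomes(ev, cfg, all = TRUE)
    acc <- out[out$accepted, ]
    if (nrow(acc) < 2) next
    # candidates are checked against accepted FINAL dates, which may drift up
    # to 14 days from the record date; the smallest table entry is 56, so no
    # two accepted record dates can ever be closer than 56 - 14 = 42 days.
    bound <- min(cfg$spacing) - cfg$reassign_window_days
    for (i in seq_len(nrow(acc) - 1)) {
      for (j in (i + 1):nrow(acc)) {
        gap <- abs(as.integer(acc$record_date[i] - acc$record_date[j]))
        expect_gte(gap, bound)
      }
    }
  }
})

test_that("events strictly after all candidate windows do not change classification", {
  set.seed(7)
  for (case in 1:50) {
    ev <- random_classifier_events()
    base <- classify_outcomes(ev, cfg)
    far <- max(ev$event_date) + 400
    ev2 <- rbind(ev, ev_row("antenatal_visit", far), ev_row("methotrexate", far),
                 ev_row("ectopic_associated", far + 1))
    expect_equal(classify_outcomes(ev2, cfg), base)
  }
})
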