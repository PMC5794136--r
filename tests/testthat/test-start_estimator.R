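cfg <- pregepi_config()

test_that("marker offsets produce the documented implied starts", {
  o <- 1000
  cases <- list(
    list(ev = ev_row("lmp", 720), method = "lmp", start = 720),
    list(ev = ev_row("fertility_dating", 733), method = "fertility", start = 720),
    list(ev = ev_row("nuchal_ultrasound", 810), method = "nuchal_ultrasound", start = 721),
    list(ev = ev_row("afp", 845), method = "afp", start = 722),
    list(ev = ev_row("amenorrhea", 775), method = "amenorrhea", start = 720),
    list(ev = ev_row("urine_test", 775), method = "urine_test", start = 720),
    list(ev = ev_row("gest_age", 790, value = 10, unit = "weeks"),
         method = "gest_age", start = 720)
  )
  for (cs in cases) {
    res <- estimate_start("live_birth", day(o), cs$ev, cfg)
    expect_equal(res$start_method, cs$method)
    expect_equal(res$start_date, day(cs$start))
    expect_equal(res$term_status, "not_applicable")
  }
  # gestational-age values expressed in days are taken as-is
  res <- estimate_start("live_birth", day(o),
                        ev_row("gest_age", 790, value = 70, unit = "days"), cfg)
  expect_equal(res$start_date, day(720))
})

test_that("with no markers the outcome-specific estimate applies, preterm-aware", {
  o <- day(1000)
  expect_equal(estimate_start("live_birth", o, ev_row("preg_confirmation", 800),
                              cfg)$start_date, o - 280)
  expect_equal(estimate_start("ectopic", o, ev_row("methotrexate", 1000),
                              cfg)$start_date, o - 56)
  expect_equal(estimate_start("stillbirth", o, ev_row("complication", 900),
                              cfg)$start_date, o - 196)
  expect_equal(estimate_start("abortion", o, ev_row("complication", 970),
                              cfg)$start_date, o - 70)

  # a preterm marker in the search window switches the live-birth estimate
  res <- estimate_start("live_birth", o, ev_row("preterm", 1000), cfg)
  expect_equal(res$term_status, "preterm")
  expect_equal(res$start_date, o - 245)
  res2 <- estimate_start("live_birth", o, ev_row("complication", 900), cfg)
  expect_equal(res2$term_status, "full_term")
})

test_that("term eligibility is strict and matches the interval oracle across the axis", {
  tw <- pregepi:::term_window_for(cfg, "live_birth")
  for (g in 150:320) {
    ev <- ev_row("lmp", 1000 - g)
    el <- eligible_markers("live_birth", day(1000), ev, cfg)
    expect_equal(nrow(el) == 1,
                 oracle_marker_eligible(g, tw$min_term_days, tw$max_term_days),
                 info = paste("gap", g))
  }
  # exactly max_term (301) and min_term (161) are ineligible
  expect_equal(nrow(eligible_markers("live_birth", day(1000),
                                     ev_row("lmp", 699), cfg)), 0)
  expect_equal(nrow(eligible_markers("live_birth", day(1000),
                                     ev_row("lmp", 839), cfg)), 0)
})

test_that("markers before the prior outcome's retry horizon are ineligible", {
  prior <- list(outcome_class = "live_birth", final_date = day(0))
  # retry for live birth is 28 days: markers dated before day 28 are out
  o <- day(250)
  for (md in c(27, 28, 29)) {
    ev <- ev_row("lmp", md)
    el <- eligible_markers("live_birth", o, ev, cfg, prior)
    expect_equal(nrow(el), as.integer(md >= 28), info = paste("marker day", md))
  }
})

test_that("the hierarchy dominates: an eligible LMP always wins", {
  set.seed(31)
  for (case in 1:60) {
    o <- day(1000)
    ev <- ev_row("lmp", 1000 - sample(162:300, 1))
    extras <- sample(c("gest_age", "fertility_dating", "nuchal_ultrasound",
                       "afp", "amenorrhea", "urine_test"), sample(0:6, 1))
    for (cat in extras) {
      d <- 1000 - sample(0:300, 1)
      ev <- rbind(ev, ev_row(cat, d, value = 12, unit = "weeks"))
    }
    res <- estimate_start("live_birth", o, ev, cfg)
    expect_equal(res$start_method, "lmp")
  }
})

test_that("within a category the earliest eligible event is used (switchable)", {
  ev <- ev_tbl(ev_row("nuchal_ultrasound", 800), ev_row("nuchal_ultrasound", 820))
  res <- estimate_start("live_birth", day(1000), ev, cfg)
  expect_equal(res$start_date, day(800 - 89))
  cfg_late <- pregepi_config(within_category_pick = "latest")
  res2 <- estimate_start("live_birth", day(1000), ev, cfg_late)
  expect_equal(res2$start_date, day(820 - 89))
})

test_that("marker-based terms sit strictly inside the window pre-clamp", {
  set.seed(55)
  for (case in 1:100) {
    cls <- sample(c("live_birth", "stillbirth", "ectopic", "abortion"), 1)
    tw <- pregepi:::term_window_for(cfg, cls)
    cat <- sample(c("lmp", "nuchal_ultrasound", "afp", "amenorrhea"), 1)
    ev <- ev_row(cat, 1000 - sample(0:320, 1))
    res <- estimate_start(cls, day(1000), ev, cfg)
    if (res$start_method != "outcome_estimate") {
      term <- as.integer(day(1000) - res$start_date)
      expect_gt(term, tw$min_term_days)
      expect_lt(term, tw$max_term_days)
    }
  }
})

test_that("starts are clamped to the prior outcome's retry period", {
  prior <- list(outcome_class = "abortion", final_date = day(0))
  # no markers: estimate would be day(200) - 280 < prior + 14
  res <- estimate_start("live_birth", day(200), ev_row("complication", 150),
                        cfg, prior)
  expect_true(res$clamped)
  expect_equal(res$start_date, day(14))

  # second-and-later episodes never start before prior + retry
  set.seed(8)
  for (case in 1:50) {
    o <- day(sample(150:400, 1))
    ev <- ev_row(sample(c("lmp", "amenorrhea", "complication"), 1),
                 sample(0:300, 1))
    res <- estimate_start("live_birth", o, ev, cfg, prior)
    expect_gte(as.integer(res$start_date - day(14)), 0)
  }
})

test_that("contraceptive and confirmation adjustments move low-confidence starts", {
  o <- day(1000)
  # amenorrhea start at day 720; contraceptive 10 days later contradicts it
  ev <- ev_tbl(ev_row("amenorrhea", 775), ev_row("contraceptive", 730))
  res <- estimate_start("live_birth", o, ev, cfg)
  expect_true(res$adjusted)
  expect_equal(res$start_date, day(731))

  # no contraceptive/confirmation events -> unchanged
  res0 <- estimate_start("live_birth", o, ev_row("amenorrhea", 775), cfg)
  expect_false(res0$adjusted)
  expect_equal(res0$start_date, day(720))

  # earliest confirmation before the estimated start pulls it back by 28 days
  ev2 <- ev_tbl(ev_row("amenorrhea", 790), ev_row("preg_confirmation", 730),
                ev_row("preg_confirmation", 900))
  res2 <- estimate_start("live_birth", o, ev2, cfg)
  expect_equal(res2$start_method, "amenorrhea")
  expect_true(res2$adjusted)
  expect_equal(res2$start_date, day(702))

  # an adjustment that would violate the maximum term is suppressed
  ev3 <- ev_tbl(ev_row("amenorrhea", 775), ev_row("preg_confirmation", 705))
  res3 <- estimate_start("live_birth", o, ev3, cfg)
  # 705 - 28 = 677 would give term 323 > 301: stays at the marker start
  expect_equal(res3$start_date, day(720))

  # high-confidence methods are never adjusted
  ev4 <- ev_tbl(ev_row("lmp", 720), ev_row("contraceptive", 730))
  res4 <- estimate_start("live_birth", o, ev4, cfg)
  expect_false(res4$adjusted)
  expect_equal(res4$start_date, day(720))
})
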