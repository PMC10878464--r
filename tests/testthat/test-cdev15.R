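test_that("timely CPR start scores correct; window anchored at recognition", {
  ev <- data.frame(t = c(27, 51), action = c("pulse_check", "start_compressions"),
                   pulse_result = c("absent", NA))
  rec <- scenario_record("T1", "aid_used", ev)
  r1 <- score_item(rec, 1)
  expect_equal(r1$status, "correct")
  expect_equal(r1$measured_time_s, 24)
  # 58 s after recognition breaches the 30 s window
  ev$t[2] <- 85
  r1b <- score_item(scenario_record("T1", "aid_used", ev), 1)
  expect_equal(r1b$status, "deviation")
  expect_match(r1b$reason, "window 30")
})

test_that("prohibition items are satisfied by inaction", {
  rec <- empty_record()
  expect_equal(score_item(rec, 14)$status, "correct")
  expect_equal(score_item(rec, 15)$status, "correct")
})

test_that("adrenaline dose tolerance is strict below 10%", {
  # 10 kg patient: correct dose 0.10 mg; 0.12 is 20% off, 0.109 is 9% off
  bad <- score_item(adrenaline_record(dose_mg = 0.12), 9)
  expect_equal(bad$status, "deviation")
  expect_match(bad$reason, "dose")
  good <- score_item(adrenaline_record(dose_mg = 0.109), 9)
  expect_equal(good$status, "correct")
  # just past 10% off is a deviation under the strict inequality
  edge <- score_item(adrenaline_record(dose_mg = 0.1101), 9)
  expect_equal(edge$status, "deviation")
  # wrong dilution, wrong route, and missing flush each break item 9
  expect_equal(score_item(adrenaline_record(dilution = 1), 9)$status, "deviation")
  expect_equal(score_item(adrenaline_record(route = "other"), 9)$status, "deviation")
  expect_equal(score_item(adrenaline_record(flush = FALSE), 9)$status, "deviation")
  # administration outside any compression episode breaks item 9
  late <- adrenaline_record(t_adm = 550)
  expect_equal(score_item(late, 9)$status, "deviation")
})

test_that("team scoring: perfect log scores 0, empty log scores 13", {
  expect_equal(score_team(perfect_record())$total, 0)
  sc <- score_team(empty_record())
  expect_equal(sc$total, 13)
  expect_equal(sc$items$status[14:15], c("correct", "correct"))
  expect_true(all(sc$items$status[1:13] == "deviation"))
  expect_true(all(nzchar(sc$items$reason[1:13])))
})

test_that("a shock and a disallowed medication add exactly two deviations", {
  rec <- perfect_record()
  extra <- data.frame(t = c(400, 420),
                      action = c("deliver_shock", "administer_medication"),
                      med_name = c(NA, "atropine"))
  rec2 <- scenario_record(rec$team_id, rec$group,
                          resusdev:::.rbind_fill(rec$events, extra),
                          rec$compressions, rec$config)
  sc <- score_team(rec2)
  expect_equal(sc$total, 2)
  expect_equal(sc$items$deviation[14], 1L)
  expect_equal(sc$items$deviation[15], 1L)
})

test_that("total equals the sum of item deviation indicators", {
  set.seed(77)
  for (i in 1:25) {
    sc <- score_team(random_log())
    expect_equal(sc$total, sum(sc$items$deviation))
    expect_true(sc$total >= 0 && sc$total <= 15)
  }
})

test_that("timed items are invariant under a common time shift", {
  rec <- perfect_record()
  base <- score_team(rec)$items$status[c(1, 2, 4, 6, 7, 8)]
  ev <- rec$events; ev$t <- ev$t + 37.5
  cp <- rec$compressions; cp$t <- cp$t + 37.5
  shifted <- scenario_record(rec$team_id, rec$group, ev, cp, rec$config)
  expect_equal(score_team(shifted)$items$status[c(1, 2, 4, 6, 7, 8)], base)
})

test_that("scorer agrees with the brute-force rule oracle on random logs", {
  set.seed(2024)
  for (i in 1:200) {
    rec <- random_log()
    expect_equal(score_team(rec)$items$status, oracle_cdev(rec),
                 info = paste("random log", i))
  }
})

test_that("cohort frequencies report correct % and its complement", {
  set.seed(9)
  coh <- simulate_cohort(cohort_params(n_no_aid = 4, n_aid = 4), seed = 9)
  fr <- cohort_item_frequencies(lapply(coh, score_team))
  expect_equal(nrow(fr), 15)
  expect_equal(fr$pct_correct + fr$pct_deviation, rep(100, 15))
  # the published CPR-board cell: 2 of 27 correct -> 92.6% deviation
  expect_equal(round(100 - 100 * 2 / 27, 1), 92.6)
  expect_error(cohort_item_frequencies(list()), "empty")
})

test_that("invalid item ids are rejected", {
  expect_error(score_item(perfect_record(), 0), "1..15")
  expect_error(score_item(perfect_record(), 16), "1..15")
})
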