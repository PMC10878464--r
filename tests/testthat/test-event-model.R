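test_that("CSV event logs parse into time-ordered records", {
  csv <- paste(
    "team_id,group,t_seconds,action,attributes",
    "T1,aid_used,27,pulse_check,pulse_result=absent",
    "T1,aid_used,51,start_compressions,",
    "T1,aid_used,70,position_board,", sep = "\n")
  rec <- read_event_log(csv, format = "csv")
  expect_s3_class(rec, "scenario_record")
  expect_equal(nrow(rec$events), 3)
  expect_equal(rec$events$action, c("pulse_check", "start_compressions",
                                    "position_board"))
  expect_equal(rec$events$t, c(27, 51, 70))
  expect_equal(rec$team_id, "T1")
})

test_that("out-of-order events are re-sorted with a warning", {
  rec0 <- perfect_record()
  txt <- write_event_log(rec0, format = "json")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  obj$events <- rev(obj$events)
  shuffled <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  expect_warning(rec <- read_event_log(shuffled, format = "json"),
                 "re-sorted")
  expect_false(is.unsorted(rec$events$t))
  # tie order among simultaneous events is not part of the contract:
  # compare under a canonical (t, action) ordering
  canon <- function(e) { e <- e[order(e$t, e$action), ]; rownames(e) <- NULL; e }
  expect_equal(canon(rec$events), canon(rec0$events))
})

test_that("missing required attributes abort with the offending line named", {
  csv <- paste(
    "team_id,group,t_seconds,action,attributes",
    "T1,aid_used,27,pulse_check,pulse_result=absent",
    "T1,aid_used,200,administer_adrenaline,route=IV", sep = "\n")
  expect_error(read_event_log(csv, format = "csv"), "line 3.*dose_mg")
})

test_that("serialization round-trips exactly in both formats", {
  recs <- list(perfect_record(), empty_record(),
               perfect_record(team_id = "équipe_α"))
  set.seed(404)
  for (i in 1:10) recs <- c(recs, list(random_log()))
  for (r in recs) {
    for (fmt in c("csv", "json")) {
      r2 <- read_event_log(write_event_log(r, format = fmt), format = fmt)
      expect_equal(r2$events, r$events)
      expect_equal(r2$compressions, r$compressions)
      expect_equal(unclass(r2$config), unclass(r$config))
      expect_identical(r2$team_id, r$team_id)
    }
  }
})

test_that("records with events past the scenario end fail validation", {
  rec <- scenario_record("T9", "aid_used",
                         data.frame(t = c(27, 601), action = c("pulse_check", "call_help"),
                                    pulse_result = c("absent", NA)))
  iss <- validate_record(rec)
  expect_true(any(iss$severity == "error"))
  at_end <- scenario_record("T9", "aid_used",
                            data.frame(t = 600, action = "call_help"))
  expect_equal(nrow(validate_record(at_end)), 0)
})

test_that("recognition time is the first absent pulse check, order-invariant", {
  ev <- data.frame(t = c(10, 25, 40),
                   action = "pulse_check",
                   pulse_result = c("present", "absent", "absent"))
  rec <- scenario_record("T1", "aid_used", ev)
  expect_equal(recognition_time(rec), 25)
  # permuting the input rows cannot change the answer
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    rec_p <- scenario_record("T1", "aid_used", ev[perm, ])
    expect_equal(recognition_time(rec_p), 25)
  }
  expect_true(is.na(recognition_time(empty_record())))
  only_present <- scenario_record("T1", "aid_used",
                                  data.frame(t = 10, action = "pulse_check",
                                             pulse_result = "present"))
  expect_true(is.na(recognition_time(only_present)))
})

test_that("synthetic records always pass validation", {
  coh <- simulate_cohort(cohort_params(n_no_aid = 3, n_aid = 3), seed = 5)
  for (r in coh) expect_equal(nrow(validate_record(r)), 0)
})
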