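test_that("cohort simulation is seeded and reproducible", {
  p <- cohort_params(n_no_aid = 3, n_aid = 2)
  a <- simulate_cohort(p, seed = 42)
  b <- simulate_cohort(p, seed = 42)
  expect_length(a, 5)
  expect_equal(vapply(a, `[[`, character(1), "group"),
               c(rep("aid_not_used", 3), rep("aid_used", 2)))
  for (i in seq_along(a)) expect_equal(a[[i]]$events, b[[i]]$events)
  c2 <- simulate_cohort(p, seed = 43)
  expect_false(identical(a[[1]]$events$t, c2[[1]]$events$t))
})

test_that("default parameters emulate the 27-team stratified cohort", {
  coh <- simulate_cohort(seed = 2)
  expect_length(coh, 27)
  grp <- table(vapply(coh, `[[`, character(1), "group"))
  expect_equal(as.integer(grp[c("aid_not_used", "aid_used")]), c(14, 13))
})

test_that("scoring a simulated record recovers the drawn indicators exactly", {
  coh <- simulate_cohort(cohort_params(n_no_aid = 10, n_aid = 10), seed = 31)
  for (r in coh) {
    drawn <- attr(r, "indicators")
    scored <- as.integer(score_team(r)$items$status == "correct")
    expect_equal(scored, drawn)
  }
})

test_that("forced probabilities produce the forced totals", {
  probs1 <- matrix(1, 15, 2, dimnames = list(NULL, c("aid_not_used", "aid_used")))
  p1 <- cohort_params(n_no_aid = 1, n_aid = 1, item_success_probs = probs1)
  for (r in simulate_cohort(p1, seed = 8))
    expect_equal(score_team(r)$total, 0)
  # all "do" items fail, prohibition items conform: total 13
  probs0 <- probs1; probs0[1:13, ] <- 0
  p0 <- cohort_params(n_no_aid = 1, n_aid = 1, item_success_probs = probs0)
  for (r in simulate_cohort(p0, seed = 8))
    expect_equal(score_team(r)$total, 13)
})

test_that("indicator draws are calibrated to the target probabilities", {
  probs <- default_item_probs()
  set.seed(505)
  for (g in colnames(probs)) {
    ind <- draw_item_indicators(probs[, g], 5000)
    expect_true(all(abs(colMeans(ind) - probs[, g]) < 0.03),
                info = paste("group", g))
  }
})

test_that("simulated task-time medians track the published targets", {
  # moderate cohort: medians are robust, 15% relative tolerance
  p <- cohort_params()
  set.seed(71)
  recs <- c(lapply(1:50, function(i) simulate_team(p, "aid_not_used", paste0("n", i))),
            lapply(1:50, function(i) simulate_team(p, "aid_used", paste0("y", i))))
  tm <- t(vapply(recs, task_times, numeric(8)))
  targ <- default_time_targets()
  for (k in targ$task) {
    md <- median(tm[, k], na.rm = TRUE)
    expect_lt(abs(md - targ$median[targ$task == k]) / targ$median[targ$task == k],
              0.15, label = paste("relative error for", k))
  }
})

test_that("rater pairs flip items at the requested rate", {
  tru <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  rp0 <- simulate_rater_pair(tru, epsilon = 0, seed = 4)
  expect_equal(rp0$rater1, as.integer(tru))
  expect_equal(rp0$rater2, as.integer(tru))
  # epsilon 0.05 over many teams: CCC of totals typically high,
  # exercising the bootstrap path
  set.seed(12)
  tot1 <- tot2 <- numeric(27)
  for (i in 1:27) {
    rp <- simulate_rater_pair(tru, 0.05)
    tot1[i] <- sum(1 - rp$rater1); tot2[i] <- sum(1 - rp$rater2)
  }
  ccc <- bootstrap_ci(function(a, b) lin_ccc(a, b)$estimate, tot1, tot2,
                      n_resamples = 500, seed = 2)
  expect_true(ccc$ci_low <= ccc$estimate && ccc$estimate <= ccc$ci_high)
})

test_that("infeasible parameter combinations are rejected", {
  expect_error(cohort_params(n_no_aid = 0, n_aid = 0))
  badp <- default_item_probs(); badp[1, 1] <- 1.5
  expect_error(cohort_params(item_success_probs = badp))
  expect_error(simulate_rater_pair(rep(1, 15), epsilon = 0.7))
})
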