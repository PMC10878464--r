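test_that("episode segmentation merges within the pause threshold", {
  one <- as_compressions(data.frame(t = seq(0, 60, by = 0.6),
                                    depth_cm = 5, release_residual_cm = 0.1))
  ep <- compression_episodes(one)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_compressions, 101L)
  two <- as_compressions(data.frame(t = c(seq(0, 30, 0.6), seq(40, 70, 0.6)),
                                    depth_cm = 5, release_residual_cm = 0.1))
  expect_equal(nrow(compression_episodes(two)), 2)
  expect_equal(nrow(compression_episodes(as_compressions(NULL))), 0)
  expect_error(compression_episodes(data.frame(t = c(5, 1), depth_cm = 5,
                                               release_residual_cm = 0.1)),
               "sorted")
})

test_that("mean rate is compressions per active minute", {
  # 90 compressions spread uniformly over one 60 s episode
  cp <- data.frame(t = seq(0, 60, length.out = 90), depth_cm = 5.5,
                   release_residual_cm = 0.1)
  ev <- data.frame(t = 0, action = "pulse_check", pulse_result = "absent")
  rec <- scenario_record("T1", "aid_used", ev, cp,
                         scenario_config(duration_s = 600))
  m <- compute_metrics(rec)
  expect_equal(m$mean_rate_per_min, 90, tolerance = 1e-10)
  expect_false(m$flags$rate_in_100_120)
  expect_equal(m$mean_depth_cm, 5.5)
  expect_true(m$flags$depth_in_5_6cm)
})

test_that("no-flow fraction follows the interval arithmetic", {
  # recognition at 30, scenario end 600, one episode covering 60-600
  cp <- data.frame(t = seq(60, 600, by = 0.5), depth_cm = 5,
                   release_residual_cm = 0)
  ev <- data.frame(t = 30, action = "pulse_check", pulse_result = "absent")
  rec <- scenario_record("T1", "aid_used", ev, cp, scenario_config())
  m <- compute_metrics(rec)
  expect_equal(m$no_flow_fraction, 30 / 570, tolerance = 1e-10)
  expect_true(m$flags$nff_lt_20pct)
  expect_equal(m$recoil_complete_fraction, 100)
  expect_true(m$flags$recoil_gt_50pct)
})

test_that("active and no-flow time conserve the resuscitation period", {
  set.seed(88)
  for (i in 1:20) {
    rec <- random_log()
    if (!nrow(rec$compressions) || is.na(recognition_time(rec))) next
    m <- compute_metrics(rec)
    expect_equal(m$active_s + m$noflow_s, m$period_s, tolerance = 1e-9)
    expect_true(m$no_flow_fraction >= 0 && m$no_flow_fraction <= 1)
  }
})

test_that("no-flow fraction agrees with a 10 ms grid oracle within 1%", {
  set.seed(99)
  checked <- 0
  while (checked < 12) {
    rec <- random_log()
    if (!nrow(rec$compressions) || is.na(recognition_time(rec))) next
    m <- compute_metrics(rec)
    expect_equal(m$no_flow_fraction, oracle_nff_grid(rec), tolerance = 0.01)
    checked <- checked + 1
  }
})

test_that("adding compressions never increases the no-flow fraction", {
  set.seed(17)
  base <- data.frame(t = sort(round(runif(100, 50, 500), 2)), depth_cm = 5,
                     release_residual_cm = 0.1)
  ev <- data.frame(t = 20, action = "pulse_check", pulse_result = "absent")
  rec <- scenario_record("T1", "aid_used", ev, base, scenario_config())
  nff0 <- compute_metrics(rec)$no_flow_fraction
  extra <- rbind(base, data.frame(t = sort(round(runif(80, 450, 590), 2)),
                                  depth_cm = 5, release_residual_cm = 0.1))
  rec2 <- scenario_record("T1", "aid_used", ev, extra, scenario_config())
  expect_lte(compute_metrics(rec2)$no_flow_fraction, nff0)
})

test_that("degenerate periods and missing anchors are errors", {
  rec <- empty_record()
  expect_error(compute_metrics(rec), "anchor")
  ev <- data.frame(t = 600, action = "pulse_check", pulse_result = "absent")
  rec2 <- scenario_record("T1", "aid_used", ev, NULL, scenario_config())
  expect_error(compute_metrics(rec2), "zero-length")
})
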