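# Seeded synthetic cohort generator. Draws per-item conformance indicators
# (Bernoulli, per group) and task times (log-normal, fitted to published
# median/IQR targets), then emits an event log and compression stream that,
# when scored by the c-DEV15plus engine, reproduce the drawn indicators
# exactly. This generator-scorer round trip is the module's central
# contract and lets the whole pipeline be exercised without recorded data.

#' Default per-group item success probabilities
#'
#' 15 x 2 matrix of per-item probabilities that the item is performed
#' correctly, columns `aid_not_used` (n = 14 reference teams) and
#' `aid_used` (n = 13), taken from the published per-group correct counts.
#'
#' @return Numeric matrix, rows items 1..15.
#' @export
default_item_probs <- function() {
  m <- cbind(aid_not_used = c(14, 0, 10, 2, 7, 11, 10, 1, 1, 2, 1, 10, 5, 13, 13) / 14,
             aid_used     = c(12, 2, 13, 1, 6, 11, 7, 1, 2, 4, 7, 11, 5, 13, 13) / 13)
  rownames(m) <- paste0("item_", 1:15)
  m
}

#' Default time-to-task distribution targets
#'
#' Published cohort medians and IQRs (seconds from scenario start) for the
#' timed resuscitation tasks; the generator fits a log-normal to each
#' (median = exp(mu); the IQR maps to sigma through the normal quartile
#' 0.6745) and draws task times from it, truncated to the side of the
#' checklist window that the drawn conformance indicator requires.
#'
#' @return data.frame with columns `task`, `median`, `q1`, `q3`.
#' @export
default_time_targets <- function() {
  data.frame(
    task = c("pulse_check", "start_cc", "start_ekg", "call_help", "bag_mask",
             "establish_iv_io", "adrenaline", "repeat_adrenaline"),
    median = c(27, 51, 57, 192.5, 70, 190, 264.5, 376),
    q1 = c(23, 33, 40, 163, 50, 130, 214, 298),
    q3 = c(38, 75, 86, 323.5, 87, 246, 293.5, 445))
}

#' Default CPR quality distribution targets
#'
#' Published cohort medians/IQRs for mean compression rate (per min), mean
#' depth (cm), complete-recoil percentage and no-flow fraction.
#'
#' @return data.frame with columns `metric`, `median`, `q1`, `q3`.
#' @export
default_compression_targets <- function() {
  data.frame(metric = c("rate", "depth", "recoil_pct", "nff"),
             median = c(85, 6.1, 45, 0.24),
             q1 = c(67, 4.6, 35, 0.18),
             q3 = c(96, 7.0, 54, 0.28))
}

#' Cohort generation parameters
#'
#' @param n_no_aid,n_aid Teams per group; defaults 14 and 13 (a 27-team
#'   cohort).
#' @param item_success_probs 15 x 2 probability matrix, columns
#'   `aid_not_used`, `aid_used`; see [default_item_probs()].
#' @param time_targets See [default_time_targets()].
#' @param compression_targets See [default_compression_targets()].
#' @param rater_flip_prob Per-item flip probability for simulated dual-rater
#'   annotations, default 0.05.
#' @param omit_prob Probability that a non-conformant "do" task is omitted
#'   entirely rather than performed late, default 0.5.
#' @param config Scenario configuration shared by all simulated teams.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_no_aid = 14, n_aid = 13,
                          item_success_probs = default_item_probs(),
                          time_targets = default_time_targets(),
                          compression_targets = default_compression_targets(),
                          rater_flip_prob = 0.05,
                          omit_prob = 0.5,
                          config = scenario_config()) {
  stopifnot(n_no_aid >= 0, n_aid >= 0, n_no_aid + n_aid >= 1,
            is.matrix(item_success_probs),
            nrow(item_success_probs) == 15,
            all(item_success_probs >= 0 & item_success_probs <= 1),
            all(c("aid_not_used", "aid_used") %in% colnames(item_success_probs)),
            rater_flip_prob >= 0, rater_flip_prob <= 0.5,
            omit_prob >= 0, omit_prob <= 1,
            inherits(config, "scenario_config"))
  structure(list(n_no_aid = n_no_aid, n_aid = n_aid,
                 item_success_probs = item_success_probs,
                 time_targets = time_targets,
                 compression_targets = compression_targets,
                 rater_flip_prob = rater_flip_prob,
                 omit_prob = omit_prob,
                 config = config),
            class = "cohort_params")
}

# log-normal parameters from a (median, q1, q3) target
.lnorm_par <- function(median, q1, q3) {
  c(meanlog = log(median),
    sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

# one draw from the target's log-normal truncated to [lo, hi] by inverse CDF
.rtrunc <- function(target, lo = 0, hi = Inf) {
  if (hi <= lo) return(lo)
  p <- .lnorm_par(target["median"], target["q1"], target["q3"])
  plo <- stats::plnorm(lo, p[1], p[2])
  phi <- stats::plnorm(hi, p[1], p[2])
  if (phi - plo < 1e-9) {
    hi_f <- if (is.finite(hi)) hi else lo + 120
    return(stats::runif(1, lo, hi_f))
  }
  stats::qlnorm(stats::runif(1, plo, phi), p[1], p[2])
}

.target_row <- function(df, key, keycol = 1) {
  r <- df[df[[keycol]] == key, ]
  stats::setNames(as.numeric(r[c("median", "q1", "q3")]), c("median", "q1", "q3"))
}

#' Draw per-team item conformance indicators
#'
#' The first stage of the generator, exposed on its own: independent
#' Bernoulli draws of the 15 item-conformance indicators (1 = correct).
#'
#' @param probs Numeric vector of 15 success probabilities.
#' @param n_teams Number of teams.
#' @return Integer matrix `n_teams` x 15 of 0/1 indicators.
#' @export
draw_item_indicators <- function(probs, n_teams) {
  stopifnot(length(probs) == 15, all(probs >= 0 & probs <= 1), n_teams >= 1)
  matrix(stats::rbinom(n_teams * 15, 1, rep(probs, each = n_teams)),
         nrow = n_teams, ncol = 15,
         dimnames = list(NULL, paste0("item_", 1:15)))
}

# build one record realising the given indicator vector; NULL on an
# infeasible internal draw (caller retries)
.build_team <- function(params, group, team_id, ind) {
  cfg <- params$config
  th <- cfg$thresholds
  dur <- cfg$duration_s
  w <- cfg$patient_weight_kg
  tt <- params$time_targets
  ct <- params$compression_targets
  omit <- function() stats::runif(1) < params$omit_prob
  ev <- list()
  add <- function(t, action, ...) {
    ev[[length(ev) + 1L]] <<- c(list(t = round(t, 2), action = action),
                                list(...))
  }

  # recognition and CPR start
  R <- .rtrunc(.target_row(tt, "pulse_check"), 5, 60)
  add(R, "pulse_check", pulse_result = "absent")
  t1 <- if (ind[1]) .rtrunc(.target_row(tt, "start_cc"), R + 12, R + th$cpr_start_s - 0.5)
        else .rtrunc(.target_row(tt, "start_cc"), R + th$cpr_start_s + 2, R + 120)
  add(t1, "start_compressions")

  # CPR quality draws
  rate <- .rtrunc(.target_row(ct, "rate"), 40, 140)
  depth_mean <- .rtrunc(.target_row(ct, "depth"), 2.5, 8.5)
  recoil_frac <- .rtrunc(.target_row(ct, "recoil_pct"), 2, 98) / 100
  nff <- .rtrunc(.target_row(ct, "nff"), 0.03, 0.55)

  # adrenaline plan -----------------------------------------------------
  # first administration window [lo1, hi1] (or omission, only when items
  # 10 and 11 are both non-conformant so the prerequisite chain may fail)
  mode9 <- "ok"
  if (!ind[9]) {
    modes <- c("late", "dose", "route", "noflush")
    if (!ind[10] && !ind[11]) modes <- c(modes, "omit")
    mode9 <- sample(modes, 1)
  }
  have_first <- mode9 != "omit"
  T1 <- NA_real_
  if (have_first) {
    lo1 <- max(t1 + 8, R + 30)
    hi1 <- if (mode9 == "late" || ind[9]) R + th$adrenaline_admin_s - 2 else dur - 40
    if (mode9 == "late") {
      lo1 <- R + th$adrenaline_admin_s + 2
      hi1 <- dur - 40
    }
    if (ind[10]) hi1 <- min(hi1, dur - th$second_call_max_s - 2)
    if (ind[11]) hi1 <- min(hi1, dur - 190)
    if (hi1 - lo1 < 5) return(NULL)
    T1 <- .rtrunc(.target_row(tt, "adrenaline"), lo1, hi1)
  }
  # second administration
  mode11 <- if (ind[11]) "ok" else sample(c("omit", "late", "dose"), 1,
                                          prob = c(0.4, 0.1, 0.5))
  if (!have_first) mode11 <- "omit"
  if (mode11 == "late" && (!have_first || T1 + th$second_admin_s + 25 > dur))
    mode11 <- "omit"
  if (mode11 == "dose" && T1 + 100 > dur - 20) mode11 <- "omit"
  T2 <- NA_real_
  if (mode11 == "ok")
    T2 <- .rtrunc(.target_row(tt, "repeat_adrenaline"),
                  T1 + 90, T1 + th$second_admin_s - 5)
  else if (mode11 == "late")
    T2 <- .rtrunc(.target_row(tt, "repeat_adrenaline"),
                  T1 + th$second_admin_s + 5, dur - 20)
  else if (mode11 == "dose")
    T2 <- .rtrunc(.target_row(tt, "repeat_adrenaline"),
                  T1 + 90, min(T1 + th$second_admin_s - 5, dur - 20))

  needed_until <- max(c(t1 + 60, T1, T2), na.rm = TRUE) + 10

  # compression stream: 15:2 cycles (or 30:2 when item 3 deviates) with
  # ventilation pauses of 2.5 s; cycles continue until the active-time
  # target implied by the drawn no-flow fraction is met and all planned
  # administrations are covered
  m <- if (ind[3]) 15L else 30L
  dt <- 60 / rate
  vp <- 2.5
  active_target <- (1 - nff) * (dur - R)
  comp_t <- numeric(0)
  vent_t <- numeric(0)
  t <- t1
  active <- 0
  repeat {
    if (t + (m - 1) * dt > dur - 8) break
    if (active >= active_target && t > needed_until) break
    cyc <- t + dt * (0:(m - 1))
    comp_t <- c(comp_t, cyc)
    last <- cyc[m]
    vent_t <- c(vent_t, last + 0.8, last + 1.7)
    active <- active + (m - 1) * dt
    t <- last + vp
  }
  if (!length(comp_t)) return(NULL)
  comp_t <- round(comp_t, 2)
  for (v in vent_t) add(v, "ventilation")
  nc <- length(comp_t)
  depths <- pmin(pmax(stats::rnorm(nc, depth_mean, 0.4), 1.8), 9)
  resid <- ifelse(stats::runif(nc) < recoil_frac,
                  stats::runif(nc, 0, th$recoil_residual_cm - 0.05),
                  stats::runif(nc, th$recoil_residual_cm + 0.1, 1.5))
  comps <- data.frame(t = comp_t, depth_cm = depths, release_residual_cm = resid)

  # snap an administration instant onto a compression in [lo, hi]
  snap <- function(target, lo, hi) {
    cand <- comp_t[comp_t >= lo & comp_t <= hi]
    if (!length(cand)) return(NA_real_)
    cand[which.min(abs(cand - target))]
  }
  dose_ok <- 0.01 * w
  if (have_first) {
    lo1s <- if (mode9 == "late") R + th$adrenaline_admin_s + 2 else max(t1, R + 30)
    hi1s <- if (mode9 == "late" || ind[9]) {
      if (mode9 == "late") dur - 30 else R + th$adrenaline_admin_s - 1
    } else dur - 30
    if (ind[10]) hi1s <- min(hi1s, dur - th$second_call_max_s - 2)
    if (ind[11]) hi1s <- min(hi1s, dur - 190)
    T1 <- snap(T1, lo1s, hi1s)
    if (is.na(T1)) return(NULL)
    add(T1, "administer_adrenaline",
        dose_mg = if (mode9 == "dose") round(dose_ok * 1.3, 4) else dose_ok,
        dilution_mg_per_ml = th$dilution_mg_per_ml,
        route = if (mode9 == "route") "other" else sample(c("IV", "IO"), 1))
    if (mode9 != "noflush") add(T1 + 3, "saline_flush")
  }
  if (!is.na(T2)) {
    lo2 <- T1 + 30
    hi2 <- if (mode11 == "late") dur - 10 else T1 + th$second_admin_s - 1
    if (mode11 == "late") lo2 <- T1 + th$second_admin_s + 2
    T2 <- snap(T2, lo2, hi2)
    if (is.na(T2)) return(NULL)
    if (mode11 == "late" && T2 - T1 <= th$second_admin_s) return(NULL)
    add(T2, "administer_adrenaline",
        dose_mg = if (mode11 == "dose") round(dose_ok * 1.3, 4) else dose_ok,
        dilution_mg_per_ml = th$dilution_mg_per_ml,
        route = sample(c("IV", "IO"), 1))
    add(T2 + 3, "saline_flush")
  }

  # adrenaline calls: item 8 (first call) and item 10 (repeat call)
  if (ind[8]) add(stats::runif(1, R + 2, R + th$adrenaline_call_s - 0.5),
                  "call_adrenaline")
  else if (!omit()) add(stats::runif(1, R + th$adrenaline_call_s + 3, R + 170),
                        "call_adrenaline")
  if (ind[10]) {
    add(T1 + stats::runif(1, th$second_call_min_s + 2,
                          th$second_call_max_s - 2), "call_adrenaline")
  } else if (have_first && !omit()) {
    tc <- T1 + stats::runif(1, 15, th$second_call_min_s - 10)
    if (tc < dur - 2) add(tc, "call_adrenaline")
  }

  # simple timed/presence items
  timed <- function(id, action, window, target = NULL, late_hi = dur - 10) {
    if (ind[id]) {
      t0 <- if (is.null(target)) stats::runif(1, R + 3, R + window - 1)
            else .rtrunc(target, R + 1, R + window - 0.5)
      add(t0, action)
    } else if (!omit()) {
      t0 <- if (is.null(target)) stats::runif(1, R + window + 4, late_hi)
            else .rtrunc(target, R + window + 3, late_hi)
      add(t0, action)
    }
  }
  timed(2, "position_board", th$board_s, late_hi = dur - 60)
  timed(4, "call_help", th$help_s, .target_row(tt, "call_help"))
  timed(6, "start_ekg_monitor", th$ekg_s, .target_row(tt, "start_ekg"))
  timed(7, "call_iv_io_access", th$iv_io_call_s, late_hi = R + 290)

  # non-checklist tasks always performed (rubric and time-table fodder)
  add(.rtrunc(.target_row(tt, "bag_mask"), R + 1, dur - 60), "start_bag_mask")
  add(.rtrunc(.target_row(tt, "establish_iv_io"), R + 20, dur - 30),
      "establish_iv_io")

  # compressor switches (item 5)
  span <- max(comp_t) - t1
  if (ind[5]) {
    add(t1 + 0.35 * span, "switch_compressor")
    add(t1 + 0.70 * span, "switch_compressor")
  } else if (stats::runif(1) < 0.5) {
    add(t1 + 0.5 * span, "switch_compressor")
  }

  if (ind[12]) add(stats::runif(1, R + 90, dur - 30), "call_blood_gas")
  if (ind[13]) for (cz in cfg$required_reversible_causes)
    add(stats::runif(1, R + 150, dur - 30), "treat_reversible_cause",
        cause_id = cz)
  if (!ind[14]) add(stats::runif(1, R + 60, dur - 30), "deliver_shock")
  if (!ind[15]) add(stats::runif(1, R + 90, dur - 20), "administer_medication",
                    med_name = sample(c("atropine", "amiodarone", "lidocaine"), 1))

  events <- do.call(.rbind_fill, lapply(ev, function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
  scenario_record(team_id, group, events, comps, cfg)
}

#' Simulate one team's scenario record
#'
#' Draws the 15 conformance indicators for the team's group, then builds an
#' event log and compression stream realising them. The built record is
#' re-scored and the build retried (new nuisance draws, same indicators) up
#' to `max_retries` times until the c-DEV15plus scoring recovers the drawn
#' indicators exactly; failure to converge is an error.
#'
#' @param params A [cohort_params()].
#' @param group `"aid_not_used"` or `"aid_used"`.
#' @param team_id Team identifier.
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @param max_retries Bounded rebuild attempts, default 25.
#' @return A `scenario_record` with the drawn indicators attached as
#'   attribute `"indicators"` (1 = correct).
#' @export
simulate_team <- function(params, group = c("aid_not_used", "aid_used"),
                          team_id = "team_01", seed = NULL, max_retries = 25) {
  stopifnot(inherits(params, "cohort_params"))
  group <- match.arg(group)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  probs <- params$item_success_probs[, group]
  ind <- as.logical(draw_item_indicators(probs, 1)[1, ])
  for (i in seq_len(max_retries)) {
    rec <- .build_team(params, group, team_id, ind)
    if (is.null(rec)) next
    sc <- score_team(rec)
    if (identical(sc$items$status == "correct", ind)) {
      attr(rec, "indicators") <- as.integer(ind)
      return(rec)
    }
  }
  stop("simulate_team: could not realise drawn indicators for ", team_id,
       " within ", max_retries, " attempts")
}

#' Simulate a full stratified cohort
#'
#' @param params A [cohort_params()]; defaults emulate the 27-team study
#'   cohort (14 teams without the cognitive aid, 13 with it).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List of `scenario_record`s with drawn indicators attached (see
#'   [simulate_team()]); `params` and `seed` are attached as attributes.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  groups <- c(rep("aid_not_used", params$n_no_aid),
              rep("aid_used", params$n_aid))
  recs <- lapply(seq_along(groups), function(i)
    simulate_team(params, groups[i], sprintf("team_%02d", i)))
  attr(recs, "params") <- params
  attr(recs, "seed") <- seed
  recs
}

#' Simulate a pair of rater annotations of an item vector
#'
#' Each rater observes the true 15-item conformance vector with independent
#' per-item flips of probability `epsilon` — the testbed for the
#' concordance (CCC) analysis.
#'
#' @param true_items 0/1 vector of length 15 (1 = correct).
#' @param epsilon Flip probability in `[0, 0.5]`.
#' @param seed Optional seed (caller RNG preserved).
#' @return List with integer vectors `rater1` and `rater2`.
#' @export
simulate_rater_pair <- function(true_items, epsilon, seed = NULL) {
  stopifnot(length(true_items) == 15, all(true_items %in% c(0, 1)),
            epsilon >= 0, epsilon <= 0.5)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  flip <- function(v) {
    f <- stats::runif(15) < epsilon
    as.integer(ifelse(f, 1 - v, v))
  }
  list(rater1 = flip(as.integer(true_items)),
       rater2 = flip(as.integer(true_items)))
}
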