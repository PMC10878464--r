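# Fixture builders and independent oracles used across the suite. The
# oracles deliberately re-derive every quantity by plain linear scans or
# exhaustive enumeration, sharing no code with the package internals they
# check.

# A fully guideline-conformant record: every "do" item timely and correct,
# no shock, no extra medication. Compressions run in 15:2 cycles from 45 s
# to the scenario end; adrenaline administrations sit exactly on
# compression instants.
perfect_record <- function(team_id = "T1", group = "aid_used") {
  cfg <- scenario_config()
  comp <- c(); vent <- c(); t <- 45
  while (t + 14 * 0.6 <= 585) {
    cyc <- t + 0.6 * (0:14)
    comp <- c(comp, cyc)
    vent <- c(vent, cyc[15] + 0.8, cyc[15] + 1.6)
    t <- cyc[15] + 2.4
  }
  comp <- round(comp, 2)
  adm1 <- comp[which.min(abs(comp - 150))]
  adm2 <- comp[which.min(abs(comp - (adm1 + 250)))]
  ev <- rbind(
    data.frame(t = 27, action = "pulse_check", pulse_result = "absent"),
    data.frame(t = 45, action = "start_compressions", pulse_result = NA),
    data.frame(t = 50, action = "position_board", pulse_result = NA),
    data.frame(t = 55, action = "start_ekg_monitor", pulse_result = NA),
    data.frame(t = 60, action = "call_help", pulse_result = NA),
    data.frame(t = 62, action = "start_bag_mask", pulse_result = NA),
    data.frame(t = 70, action = "call_iv_io_access", pulse_result = NA),
    data.frame(t = 40, action = "call_adrenaline", pulse_result = NA),
    data.frame(t = 120, action = "establish_iv_io", pulse_result = NA),
    data.frame(t = 300, action = "call_blood_gas", pulse_result = NA),
    data.frame(t = 100, action = "switch_compressor", pulse_result = NA),
    data.frame(t = 320, action = "switch_compressor", pulse_result = NA))
  ev$dose_mg <- NA_real_; ev$dilution_mg_per_ml <- NA_real_
  ev$route <- NA_character_; ev$cause_id <- NA_character_
  ev$med_name <- NA_character_
  add <- function(df, t, action, ...) {
    row <- ev[1, ]; row[] <- NA
    row$t <- t; row$action <- action
    extra <- list(...)
    for (k in names(extra)) row[[k]] <- extra[[k]]
    rbind(df, row)
  }
  ev <- add(ev, adm1, "administer_adrenaline", dose_mg = 0.1,
            dilution_mg_per_ml = 0.1, route = "IV")
  ev <- add(ev, adm1 + 3, "saline_flush")
  ev <- add(ev, adm1 + 200, "call_adrenaline")
  ev <- add(ev, adm2, "administer_adrenaline", dose_mg = 0.1,
            dilution_mg_per_ml = 0.1, route = "IO")
  ev <- add(ev, adm2 + 3, "saline_flush")
  ev <- add(ev, 430, "treat_reversible_cause", cause_id = "hypoglycemia")
  for (v in vent) ev <- add(ev, v, "ventilation")
  comps <- data.frame(t = comp, depth_cm = 5.4, release_residual_cm = 0.1)
  scenario_record(team_id, group, ev, comps, cfg)
}

empty_record <- function(team_id = "E1", group = "aid_not_used") {
  scenario_record(team_id, group, NULL, NULL, scenario_config())
}

# a record with recognition, active compressions around t = 150 and a
# first adrenaline administration with controllable attributes
adrenaline_record <- function(dose_mg = 0.1, dilution = 0.1, route = "IV",
                              flush = TRUE, t_adm = 150, weight = 10) {
  cfg <- scenario_config(patient_weight_kg = weight)
  comp <- round(seq(50, 400, by = 0.6), 2)
  ev <- data.frame(t = c(27, 50, t_adm),
                   action = c("pulse_check", "start_compressions",
                              "administer_adrenaline"),
                   pulse_result = c("absent", NA, NA),
                   dose_mg = c(NA, NA, dose_mg),
                   dilution_mg_per_ml = c(NA, NA, dilution),
                   route = c(NA, NA, route))
  if (flush) ev <- rbind(ev, data.frame(t = t_adm + 4, action = "saline_flush",
                                        pulse_result = NA, dose_mg = NA,
                                        dilution_mg_per_ml = NA, route = NA))
  scenario_record("A1", "aid_used", ev,
                  data.frame(t = comp, depth_cm = 5, release_residual_cm = 0.2),
                  cfg)
}

# random event-soup records for oracle comparison: arbitrary but valid
random_log <- function() {
  cfg <- scenario_config()
  n <- sample(0:40, 1)
  acts <- sample(action_kinds(), n, replace = TRUE)
  ev <- data.frame(t = round(stats::runif(n, 0, 600), 2), action = acts,
                   stringsAsFactors = FALSE)
  ev$pulse_result <- ifelse(acts == "pulse_check",
                            sample(c("present", "absent"), n, replace = TRUE), NA)
  ev$dose_mg <- ifelse(acts == "administer_adrenaline",
                       round(stats::runif(n, 0.05, 0.2), 3), NA)
  ev$dilution_mg_per_ml <- ifelse(acts == "administer_adrenaline",
                                  sample(c(0.1, 1), n, replace = TRUE), NA)
  ev$route <- ifelse(acts == "administer_adrenaline",
                     sample(c("IV", "IO", "other"), n, replace = TRUE), NA)
  ev$cause_id <- ifelse(acts == "treat_reversible_cause",
                        sample(c("hypoglycemia", "hypoxia"), n, replace = TRUE), NA)
  ev$med_name <- ifelse(acts == "administer_medication",
                        sample(c("atropine", "amiodarone", "dextrose"), n,
                               replace = TRUE), NA)
  k <- sample(c(0, 0, 30, 120, 300), 1)
  comps <- if (k > 0) {
    tt <- sort(round(stats::runif(k, 0, 600), 2))
    depth <- stats::runif(k, 2, 8)
    data.frame(t = tt, depth_cm = depth,
               release_residual_cm = pmin(stats::runif(k, 0, 1.4), depth - 0.1))
  } else NULL
  scenario_record("R1", sample(c("aid_used", "aid_not_used"), 1),
                  if (n > 0) ev else NULL, comps, cfg)
}

# ---- independent oracles ---------------------------------------------------

# brute-force re-evaluation of the 15 checklist rules by linear scans
oracle_cdev <- function(record) {
  ev <- record$events
  th <- record$config$thresholds
  cfg <- record$config
  rec <- NA_real_
  for (i in seq_len(nrow(ev)))
    if (ev$action[i] == "pulse_check" && identical(ev$pulse_result[i], "absent")) {
      rec <- ev$t[i]; break
    }
  tfirst <- function(a) {
    out <- Inf
    for (i in seq_len(nrow(ev))) if (ev$action[i] == a) out <- min(out, ev$t[i])
    out
  }
  ok <- logical(15)
  win <- function(a, w) !is.na(rec) && tfirst(a) - rec <= w
  ok[1] <- win("start_compressions", th$cpr_start_s)
  ok[2] <- win("position_board", th$board_s)
  ok[4] <- win("call_help", th$help_s)
  ok[6] <- win("start_ekg_monitor", th$ekg_s)
  ok[7] <- win("call_iv_io_access", th$iv_io_call_s)
  ok[8] <- win("call_adrenaline", th$adrenaline_call_s)
  # item 3: walk a merged C/V timeline
  ct0 <- record$compressions$t
  vt0 <- ev$t[ev$action == "ventilation"]
  marks <- data.frame(t = c(ct0, vt0),
                      k = c(rep("C", length(ct0)), rep("V", length(vt0))))
  marks <- marks[order(marks$t), ]
  cycles <- list(); nc <- 0; nv <- 0; in_vent <- FALSE
  for (i in seq_len(nrow(marks))) {
    if (marks$k[i] == "C") {
      if (in_vent) { cycles[[length(cycles) + 1]] <- c(nc, nv); nc <- 0; nv <- 0 }
      in_vent <- FALSE; nc <- nc + 1
    } else if (nc > 0) { in_vent <- TRUE; nv <- nv + 1 }
  }
  if (in_vent && nc > 0) cycles[[length(cycles) + 1]] <- c(nc, nv)
  if (length(cycles)) {
    good <- vapply(cycles, function(cy)
      cy[1] >= th$ratio_low && cy[1] <= th$ratio_high && cy[2] == 2, logical(1))
    ok[3] <- mean(good) >= th$ratio_fraction
  }
  # item 5
  firstc <- Inf
  if (nrow(record$compressions)) firstc <- record$compressions$t[1]
  firstc <- min(firstc, tfirst("start_compressions"))
  if (is.finite(firstc)) {
    nsw <- 0
    for (i in seq_len(nrow(ev)))
      if (ev$action[i] == "switch_compressor" && ev$t[i] >= firstc) nsw <- nsw + 1
    ok[5] <- nsw >= 2
  }
  # compression episodes by linear gap walk
  eps <- list()
  ct <- record$compressions$t
  if (length(ct)) {
    s <- ct[1]; e <- ct[1]
    for (i in seq_along(ct)[-1]) {
      if (ct[i] - e > th$pause_threshold_s) { eps[[length(eps) + 1]] <- c(s, e); s <- ct[i] }
      e <- ct[i]
    }
    eps[[length(eps) + 1]] <- c(s, e)
  }
  in_episode <- function(t0) {
    for (p in eps) if (t0 >= p[1] && t0 <= p[2]) return(TRUE)
    FALSE
  }
  adren_ok <- function(i) {
    t0 <- ev$t[i]
    target <- 0.01 * cfg$patient_weight_kg
    dose <- ev$dose_mg[i]
    flushed <- FALSE
    for (j in seq_len(nrow(ev)))
      if (ev$action[j] == "saline_flush" && ev$t[j] > t0 &&
          ev$t[j] <= t0 + th$flush_window_s) flushed <- TRUE
    !is.na(dose) && abs(dose - target) / target < th$dose_tolerance &&
      !is.na(ev$dilution_mg_per_ml[i]) &&
      abs(ev$dilution_mg_per_ml[i] - th$dilution_mg_per_ml) < 1e-9 &&
      ev$route[i] %in% c("IV", "IO") && flushed && in_episode(t0)
  }
  adm <- which(ev$action == "administer_adrenaline")
  if (length(adm) && !is.na(rec))
    ok[9] <- adren_ok(adm[1]) && ev$t[adm[1]] - rec <= th$adrenaline_admin_s
  if (length(adm)) {
    t1 <- ev$t[adm[1]]
    for (i in seq_len(nrow(ev)))
      if (ev$action[i] == "call_adrenaline" &&
          ev$t[i] - t1 >= th$second_call_min_s &&
          ev$t[i] - t1 <= th$second_call_max_s) ok[10] <- TRUE
    if (length(adm) >= 2)
      ok[11] <- adren_ok(adm[2]) && ev$t[adm[2]] - t1 <= th$second_admin_s
  }
  ok[12] <- any(ev$action == "call_blood_gas")
  treated <- ev$cause_id[ev$action == "treat_reversible_cause"]
  ok[13] <- all(cfg$required_reversible_causes %in% treated)
  ok[14] <- !any(ev$action == "deliver_shock")
  med <- ev$med_name[ev$action == "administer_medication"]
  ok[15] <- all(med %in% cfg$allowed_cause_medications)
  ifelse(ok, "correct", "deviation")
}

# direct hypergeometric enumeration for a 2x2 table (point-probability rule)
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# exact two-sided rank-sum p by exhaustive subset enumeration (no ties)
oracle_wilcox_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(m)])
  sums <- utils::combn(N, m, FUN = sum)  # rank labels are 1..N (no ties)
  p_le <- mean(sums <= wobs); p_ge <- mean(sums >= wobs)
  min(1, 2 * min(p_le, p_ge))
}

# 10 ms grid discretization of the no-flow computation
oracle_nff_grid <- function(record, step = 0.01) {
  rec <- recognition_time(record)
  dur <- record$config$duration_s
  ep <- compression_episodes(record$compressions,
                             record$config$thresholds$pause_threshold_s)
  grid <- seq(rec, dur, by = step)
  covered <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(ep)))
    covered <- covered | (grid >= ep$start_s[i] & grid <= ep$end_s[i])
  1 - mean(covered)
}
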