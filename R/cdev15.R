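# c-DEV15plus: 15-item binary checklist counting deviations (omissions,
# errors, delays) from pediatric advanced life support recommendations in a
# nonshockable arrest scenario. Each item scores 0 when the task is well and
# timely performed and 1 (a deviation) otherwise; the total runs from 0
# (no deviation) to 15.

#' c-DEV15plus item labels
#'
#' @return data.frame with columns `item` (1..15) and `label`.
#' @export
cdev15_items <- function() {
  data.frame(item = 1:15, label = c(
    "CPR started within 30 s from recognition of pulseless state",
    "CPR board positioned within 60 s from recognition of pulseless state",
    "Compression:ventilation ratio 15:2",
    "Help called within 60 s from recognition of pulseless state",
    "Compressors switched more than once during CPR",
    "EKG monitoring started within 60 s from recognition of pulseless state",
    "IV/IO access called within 60 s from recognition of pulseless state",
    "First adrenaline called within 30 s from recognition of pulseless state",
    "First adrenaline administered correctly within 180 s from recognition",
    "Second adrenaline called between 3 and 5 min from first administration",
    "Second adrenaline administered correctly within 5 min of the first",
    "Blood gas called during cardiac arrest",
    "Reversible causes treated",
    "Shock not administered",
    "Medications other than adrenaline not administered"))
}

.item_result <- function(item_id, correct, reason_dev, measured = NA_real_) {
  list(item_id = item_id,
       status = if (correct) "correct" else "deviation",
       reason = if (correct) "" else reason_dev,
       measured_time_s = measured)
}

.first_time <- function(ev, kind, keep = NULL) {
  sel <- ev$action == kind
  if (!is.null(keep)) sel <- sel & keep(ev)
  if (!any(sel)) NA_real_ else min(ev$t[sel])
}

# timed "do X within window of recognition" items
.timed_item <- function(item_id, ev, rec, kind, window, what) {
  if (is.na(rec))
    return(.item_result(item_id, FALSE, "pulseless state never recognized"))
  t <- .first_time(ev, kind)
  if (is.na(t))
    return(.item_result(item_id, FALSE, paste0(what, " never performed")))
  elapsed <- t - rec
  .item_result(item_id, elapsed <= window,
               sprintf("%s at %.1f s after recognition (window %.0f s)",
                       what, elapsed, window),
               measured = elapsed)
}

# ventilation-cycle decomposition used by item 3: a completed cycle is a run
# of compressions followed by a burst of ventilation events
.cycles <- function(record) {
  cp_t <- record$compressions$t
  vt_t <- record$events$t[record$events$action == "ventilation"]
  if (!length(cp_t) || !length(vt_t)) return(NULL)
  times <- c(cp_t, vt_t)
  kind <- c(rep("C", length(cp_t)), rep("V", length(vt_t)))
  o <- order(times)
  kind <- kind[o]
  r <- rle(kind)
  cycles <- list()
  i <- 1
  while (i < length(r$values)) {
    if (r$values[i] == "C" && r$values[i + 1] == "V") {
      cycles[[length(cycles) + 1L]] <-
        c(n_comp = r$lengths[i], n_vent = r$lengths[i + 1])
    }
    i <- i + 1
  }
  if (!length(cycles)) NULL else do.call(rbind, cycles)
}

# quality conditions shared by items 9 and 11: dose within tolerance of
# 0.01 mg/kg, 0.1 mg/ml dilution, IV/IO route, saline flush afterwards,
# administered while a compression episode is active
.adrenaline_quality <- function(record, t_adm, row, th) {
  w <- record$config$patient_weight_kg
  target <- 0.01 * w
  fails <- character(0)
  if (is.na(row$dose_mg) ||
      !(abs(row$dose_mg - target) / target < th$dose_tolerance))
    fails <- c(fails, sprintf("dose %.3f mg outside <%.0f%% of %.3f mg",
                              row$dose_mg, 100 * th$dose_tolerance, target))
  if (is.na(row$dilution_mg_per_ml) ||
      abs(row$dilution_mg_per_ml - th$dilution_mg_per_ml) > 1e-9)
    fails <- c(fails, sprintf("dilution %.3g mg/ml is not %.3g mg/ml",
                              row$dilution_mg_per_ml, th$dilution_mg_per_ml))
  if (is.na(row$route) || !row$route %in% c("IV", "IO"))
    fails <- c(fails, sprintf("route '%s' is not IV or IO", row$route))
  fl <- record$events$t[record$events$action == "saline_flush"]
  if (!any(fl > t_adm & fl <= t_adm + th$flush_window_s))
    fails <- c(fails, sprintf("no saline flush within %.0f s after administration",
                              th$flush_window_s))
  ep <- compression_episodes(record$compressions, th$pause_threshold_s)
  active <- nrow(ep) > 0 && any(t_adm >= ep$start_s & t_adm <= ep$end_s)
  if (!active) fails <- c(fails, "not administered while compressions active")
  fails
}

#' Score one c-DEV15plus item
#'
#' Evaluates a single checklist item against a scenario record. Items
#' anchored at recognition of the pulseless state (1, 2, 4, 6, 7, 8, 9)
#' are deviations when the pulseless state was never recognised; items 10
#' and 11 are deviations when no first adrenaline was ever administered
#' (the prerequisite task chain never completed). Time-window comparisons
#' are inclusive.
#'
#' @param record A validated [scenario_record()].
#' @param item_id Integer 1..15.
#' @return A list with `item_id`, `status` (`"correct"`/`"deviation"`),
#'   `reason` (non-empty on deviation) and `measured_time_s` where a time
#'   was measured.
#' @export
score_item <- function(record, item_id) {
  stopifnot(inherits(record, "scenario_record"))
  if (!is.numeric(item_id) || length(item_id) != 1L || !item_id %in% 1:15)
    stop("item_id must be a single integer in 1..15")
  item_id <- as.integer(item_id)
  ev <- record$events
  th <- record$config$thresholds
  rec <- recognition_time(record)
  dur <- record$config$duration_s

  if (item_id == 1L)
    return(.timed_item(1L, ev, rec, "start_compressions", th$cpr_start_s, "CPR start"))
  if (item_id == 2L)
    return(.timed_item(2L, ev, rec, "position_board", th$board_s, "CPR board positioning"))
  if (item_id == 4L)
    return(.timed_item(4L, ev, rec, "call_help", th$help_s, "call for help"))
  if (item_id == 6L)
    return(.timed_item(6L, ev, rec, "start_ekg_monitor", th$ekg_s, "EKG monitoring start"))
  if (item_id == 7L)
    return(.timed_item(7L, ev, rec, "call_iv_io_access", th$iv_io_call_s, "IV/IO access call"))
  if (item_id == 8L)
    return(.timed_item(8L, ev, rec, "call_adrenaline", th$adrenaline_call_s, "first adrenaline call"))

  if (item_id == 3L) {
    cyc <- .cycles(record)
    if (is.null(cyc))
      return(.item_result(3L, FALSE, "no completed compression-ventilation cycles"))
    ok <- cyc[, "n_comp"] >= th$ratio_low & cyc[, "n_comp"] <= th$ratio_high &
      cyc[, "n_vent"] == 2
    frac <- mean(ok)
    return(.item_result(3L, frac >= th$ratio_fraction,
                        sprintf("only %.0f%% of %d cycles conform to 15:2",
                                100 * frac, nrow(cyc)),
                        measured = frac))
  }

  if (item_id == 5L) {
    first_c <- suppressWarnings(min(c(record$compressions$t,
                                      .first_time(ev, "start_compressions")), na.rm = TRUE))
    if (!is.finite(first_c))
      return(.item_result(5L, FALSE, "CPR never started"))
    n_sw <- sum(ev$action == "switch_compressor" & ev$t >= first_c)
    return(.item_result(5L, n_sw >= 2,
                        sprintf("compressors switched %d time(s); more than once required", n_sw)))
  }

  if (item_id == 9L) {
    if (is.na(rec))
      return(.item_result(9L, FALSE, "pulseless state never recognized"))
    adm <- which(ev$action == "administer_adrenaline")
    if (!length(adm))
      return(.item_result(9L, FALSE, "adrenaline never administered"))
    i1 <- adm[1]
    t1 <- ev$t[i1]
    fails <- .adrenaline_quality(record, t1, ev[i1, ], th)
    if (t1 - rec > th$adrenaline_admin_s)
      fails <- c(fails, sprintf("administered %.1f s after recognition (window %.0f s)",
                                t1 - rec, th$adrenaline_admin_s))
    return(.item_result(9L, length(fails) == 0L,
                        paste(fails, collapse = "; "), measured = t1 - rec))
  }

  if (item_id == 10L) {
    adm <- ev$t[ev$action == "administer_adrenaline"]
    if (!length(adm))
      return(.item_result(10L, FALSE, "first adrenaline never administered"))
    t1 <- adm[1]
    calls <- ev$t[ev$action == "call_adrenaline"]
    dt <- calls - t1
    hit <- any(dt >= th$second_call_min_s & dt <= th$second_call_max_s)
    return(.item_result(10L, hit,
                        sprintf("no adrenaline call in [%.0f, %.0f] s after first administration",
                                th$second_call_min_s, th$second_call_max_s)))
  }

  if (item_id == 11L) {
    adm <- which(ev$action == "administer_adrenaline")
    if (!length(adm))
      return(.item_result(11L, FALSE, "first adrenaline never administered"))
    if (length(adm) < 2L)
      return(.item_result(11L, FALSE, "second adrenaline never administered"))
    t1 <- ev$t[adm[1]]
    i2 <- adm[2]
    t2 <- ev$t[i2]
    fails <- .adrenaline_quality(record, t2, ev[i2, ], th)
    if (t2 - t1 > th$second_admin_s)
      fails <- c(fails, sprintf("second dose %.1f s after first (window %.0f s)",
                                t2 - t1, th$second_admin_s))
    return(.item_result(11L, length(fails) == 0L,
                        paste(fails, collapse = "; "), measured = t2 - t1))
  }

  if (item_id == 12L) {
    hit <- any(ev$action == "call_blood_gas")
    return(.item_result(12L, hit, "blood gas never called"))
  }

  if (item_id == 13L) {
    need <- record$config$required_reversible_causes
    treated <- unique(ev$cause_id[ev$action == "treat_reversible_cause"])
    missing <- setdiff(need, treated)
    return(.item_result(13L, length(missing) == 0L,
                        paste0("reversible cause(s) not treated: ",
                               paste(missing, collapse = ", "))))
  }

  if (item_id == 14L) {
    n <- sum(ev$action == "deliver_shock")
    return(.item_result(14L, n == 0L,
                        sprintf("%d shock(s) delivered in a nonshockable rhythm", n)))
  }

  # item 15
  med <- ev[ev$action == "administer_medication", , drop = FALSE]
  allowed <- record$config$allowed_cause_medications
  bad <- med$med_name[!med$med_name %in% allowed]
  .item_result(15L, length(bad) == 0L,
               paste0("disallowed medication(s) administered: ",
                      paste(unique(bad), collapse = ", ")))
}

#' Score a team on the full c-DEV15plus checklist
#'
#' @param record A validated [scenario_record()].
#' @return Object of class `cdev_score`: list with `team_id`, `group`,
#'   `items` (data.frame: item, label, status, deviation 0/1, reason,
#'   measured_time_s) and `total` (number of deviations, 0..15).
#' @export
score_team <- function(record) {
  res <- lapply(1:15, function(i) score_item(record, i))
  items <- cdev15_items()
  items$status <- vapply(res, `[[`, character(1), "status")
  items$deviation <- as.integer(items$status == "deviation")
  items$reason <- vapply(res, `[[`, character(1), "reason")
  items$measured_time_s <- vapply(res, `[[`, numeric(1), "measured_time_s")
  structure(list(team_id = record$team_id, group = record$group,
                 items = items, total = sum(items$deviation)),
            class = "cdev_score")
}

#' @export
print.cdev_score <- function(x, ...) {
  cat(sprintf("<cdev_score> team %s (%s): %d/15 deviations\n",
              x$team_id, x$group, x$total))
  dev <- x$items[x$items$deviation == 1L, ]
  for (i in seq_len(nrow(dev)))
    cat(sprintf("  item %2d: %s\n", dev$item[i], dev$reason[i]))
  invisible(x)
}

#' Per-item correct/deviation frequencies across a cohort
#'
#' @param scores Non-empty list of [score_team()] results.
#' @return data.frame with, per item: `n_correct`, `pct_correct` and
#'   `pct_deviation` (the complement of 100%).
#' @export
cohort_item_frequencies <- function(scores) {
  if (!length(scores)) stop("empty score list")
  stopifnot(all(vapply(scores, inherits, logical(1), "cdev_score")))
  m <- vapply(scores, function(s) s$items$deviation, integer(15))
  n <- length(scores)
  out <- cdev15_items()
  out$n_correct <- rowSums(1L - m)
  out$pct_correct <- 100 * out$n_correct / n
  out$pct_deviation <- 100 - out$pct_correct
  out
}
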