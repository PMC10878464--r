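# Event-log data model: scenario configuration, action events, compression
# stream, validation and (de)serialization. Everything downstream (checklist
# scoring, rubric scoring, CPR metrics, the study pipeline) consumes the
# scenario_record built here.

#' Recognised action kinds
#'
#' The controlled vocabulary of resuscitation actions an event log may
#' contain. Unknown kinds are preserved on read but flagged as warnings by
#' [validate_record()].
#'
#' @return Character vector of action kind names.
#' @export
action_kinds <- function() {
  c("pulse_check", "start_compressions", "stop_compressions",
    "position_board", "call_help", "start_ekg_monitor", "call_iv_io_access",
    "establish_iv_io", "call_adrenaline", "administer_adrenaline",
    "saline_flush", "call_blood_gas", "treat_reversible_cause",
    "deliver_shock", "administer_medication", "ventilation",
    "switch_compressor", "start_bag_mask")
}

# attribute columns carried on every events data.frame
.attr_cols <- c("pulse_result", "dose_mg", "dilution_mg_per_ml", "route",
                "cause_id", "med_name")
.num_attrs <- c("dose_mg", "dilution_mg_per_ml")

#' Default scoring thresholds
#'
#' Time windows and tolerances used by the c-DEV15plus checklist and the CPR
#' quality metrics. All windows are inclusive ("within 60 s" means elapsed
#' time \eqn{\le 60}). Units: seconds, centimetres, mg/ml, or dimensionless
#' fractions.
#'
#' @param ... Named overrides of individual thresholds.
#'
#' @details The defaults encode the checklist's published windows: CPR and
#' the first adrenaline call within 30 s of recognition of the pulseless
#' state; CPR board, call for help, EKG monitoring and the IV/IO call within
#' 60 s; first adrenaline administered within 180 s; the second adrenaline
#' call between 180 and 300 s after the first administration and the second
#' administration within 300 s of the first. The correct adrenaline dose is
#' 0.01 mg/kg with a strict relative tolerance of less than 10%, at a
#' 1:10,000 dilution (0.1 mg/ml). Operational constants the source checklist
#' leaves to the rater are explicit here: a compression pause longer than
#' `pause_threshold_s` splits compression episodes, a release residual of at
#' most `recoil_residual_cm` counts as complete chest recoil, a saline flush
#' must follow an adrenaline administration within `flush_window_s`, and a
#' 15:2 cycle is accepted when its compression count lies in
#' `[ratio_low, ratio_high]` with at least `ratio_fraction` of completed
#' cycles conforming.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(...) {
  th <- list(
    cpr_start_s          = 30,
    board_s              = 60,
    help_s               = 60,
    ekg_s                = 60,
    iv_io_call_s         = 60,
    adrenaline_call_s    = 30,
    adrenaline_admin_s   = 180,
    second_call_min_s    = 180,
    second_call_max_s    = 300,
    second_admin_s       = 300,
    dose_tolerance       = 0.10,
    dilution_mg_per_ml   = 0.1,
    flush_window_s       = 30,
    ratio_low            = 13,
    ratio_high           = 17,
    ratio_fraction       = 0.8,
    pause_threshold_s    = 2.0,
    recoil_residual_cm   = 0.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    th[names(dots)] <- dots
  }
  stopifnot(all(vapply(th, function(x) is.numeric(x) && x > 0, logical(1))))
  th
}

#' Scenario configuration
#'
#' Static description of the simulated scenario against which an event log is
#' scored: patient weight, scenario duration, arrest rhythm, the reversible
#' causes the scenario programmes, and the scoring thresholds.
#'
#' @param patient_weight_kg Simulated patient weight in kg (> 0). Default 10;
#'   the value is a package default, not a clinical constant, and should be
#'   set from the scenario script in use.
#' @param duration_s Scenario length in seconds from start; default 600
#'   (a 10-minute scenario).
#' @param rhythm `"nonshockable"` or `"shockable"`. The shipped checklist is
#'   defined for nonshockable arrest.
#' @param required_reversible_causes Character vector of cause identifiers
#'   the team is expected to treat. Default a single cause,
#'   `"hypoglycemia"`.
#' @param allowed_cause_medications Medications that treat a programmed
#'   reversible cause and therefore do not count as disallowed medications.
#' @param thresholds Threshold list, see [default_thresholds()].
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(patient_weight_kg = 10,
                            duration_s = 600,
                            rhythm = c("nonshockable", "shockable"),
                            required_reversible_causes = "hypoglycemia",
                            allowed_cause_medications = "dextrose",
                            thresholds = default_thresholds()) {
  rhythm <- match.arg(rhythm)
  stopifnot(is.numeric(patient_weight_kg), patient_weight_kg > 0,
            is.numeric(duration_s), duration_s > 0)
  required_reversible_causes <- as.character(required_reversible_causes)
  allowed_cause_medications <- as.character(allowed_cause_medications)
  structure(list(patient_weight_kg = patient_weight_kg,
                 duration_s = duration_s,
                 rhythm = rhythm,
                 required_reversible_causes = required_reversible_causes,
                 allowed_cause_medications = allowed_cause_medications,
                 thresholds = thresholds),
            class = "scenario_config")
}

#' Build an events table
#'
#' Normalises a data.frame of action events to the canonical column layout:
#' `t`, `action`, plus the attribute columns `pulse_result`, `dose_mg`,
#' `dilution_mg_per_ml`, `route`, `cause_id`, `med_name` (NA where not
#' applicable). Rows are sorted by time.
#'
#' @param df data.frame with at least `t` and `action`.
#' @return Canonical events data.frame.
#' @export
as_events <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    out <- data.frame(t = numeric(0), action = character(0),
                      stringsAsFactors = FALSE)
    for (a in .attr_cols) out[[a]] <- if (a %in% .num_attrs) numeric(0) else character(0)
    return(out)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("t", "action") %in% names(df)))
  out <- data.frame(t = as.numeric(df$t), action = as.character(df$action),
                    stringsAsFactors = FALSE)
  for (a in .attr_cols) {
    v <- if (a %in% names(df)) df[[a]] else rep(NA, nrow(df))
    out[[a]] <- if (a %in% .num_attrs) as.numeric(v) else as.character(v)
  }
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a compressions table
#'
#' Normalises a chest-compression stream: one row per compression with `t`
#' (instant of maximal displacement, seconds), `depth_cm` (> 0) and
#' `release_residual_cm` (residual displacement at release, >= 0).
#'
#' @param df data.frame (or NULL for an empty stream).
#' @return Canonical compressions data.frame sorted by `t`.
#' @export
as_compressions <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    return(data.frame(t = numeric(0), depth_cm = numeric(0),
                      release_residual_cm = numeric(0)))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("t", "depth_cm", "release_residual_cm") %in% names(df)))
  out <- data.frame(t = as.numeric(df$t),
                    depth_cm = as.numeric(df$depth_cm),
                    release_residual_cm = as.numeric(df$release_residual_cm))
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One team's scenario record
#'
#' Bundles a team's full event log, compression stream and scenario
#' configuration. Events and compressions are sorted by time on
#' construction.
#'
#' @param team_id Team identifier, unique within a cohort.
#' @param group `"aid_used"` or `"aid_not_used"` — whether the team used the
#'   pocket-card cognitive aid.
#' @param events Events data.frame (see [as_events()]).
#' @param compressions Compression stream (see [as_compressions()]).
#' @param config A [scenario_config()].
#'
#' @return Object of class `scenario_record`.
#' @export
scenario_record <- function(team_id, group = c("aid_not_used", "aid_used"),
                            events = NULL, compressions = NULL,
                            config = scenario_config()) {
  group <- match.arg(group)
  stopifnot(is.character(team_id), length(team_id) == 1L, nzchar(team_id),
            inherits(config, "scenario_config"))
  structure(list(team_id = team_id, group = group,
                 events = as_events(events),
                 compressions = as_compressions(compressions),
                 config = config),
            class = "scenario_record")
}

#' @export
print.scenario_record <- function(x, ...) {
  cat(sprintf("<scenario_record> team %s (%s): %d events, %d compressions, %.0f s scenario\n",
              x$team_id, x$group, nrow(x$events), nrow(x$compressions),
              x$config$duration_s))
  invisible(x)
}

# required attributes per action kind
.required_attrs <- list(
  pulse_check = "pulse_result",
  administer_adrenaline = c("dose_mg", "dilution_mg_per_ml", "route"),
  treat_reversible_cause = "cause_id",
  administer_medication = "med_name"
)

#' Validate a scenario record
#'
#' Structural and semantic checks on a [scenario_record()]: event times
#' within `[0, duration_s]` (events exactly at the scenario end are in
#' scope, later ones are errors), required attributes present for their
#' action kind, known action vocabulary (unknown kinds are warnings, not
#' errors), compression stream sorted with depth exceeding the release
#' residual.
#'
#' @param record A `scenario_record`.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `where` (event index or field name) and `message`; zero rows when the
#'   record is fully valid.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "scenario_record"))
  iss <- list()
  add <- function(severity, where, message) {
    iss[[length(iss) + 1L]] <<- data.frame(severity = severity,
                                           where = as.character(where),
                                           message = message)
  }
  ev <- record$events
  dur <- record$config$duration_s
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (is.na(e$t) || e$t < 0) add("error", i, sprintf("event %d: negative or missing time", i))
    else if (e$t > dur) add("error", i, sprintf("event %d (%s): t=%.1f after scenario end (%.0f s)", i, e$action, e$t, dur))
    if (!e$action %in% action_kinds())
      add("warning", i, sprintf("event %d: unknown action kind '%s'", i, e$action))
    req <- .required_attrs[[e$action]]
    for (a in req) {
      if (is.na(e[[a]]))
        add("error", i, sprintf("event %d (%s): missing required attribute '%s'", i, e$action, a))
    }
    if (e$action == "pulse_check" && !is.na(e$pulse_result) &&
        !e$pulse_result %in% c("present", "absent"))
      add("error", i, sprintf("event %d: pulse_result must be 'present' or 'absent', got '%s'", i, e$pulse_result))
  }
  cp <- record$compressions
  if (nrow(cp)) {
    if (is.unsorted(cp$t)) add("error", "compressions", "compression stream not sorted by time")
    bad <- which(!(cp$depth_cm > cp$release_residual_cm))
    if (length(bad))
      add("error", "compressions",
          sprintf("compression(s) %s: depth_cm must exceed release_residual_cm",
                  paste(utils::head(bad, 5), collapse = ",")))
    if (any(cp$t < 0 | cp$t > dur))
      add("error", "compressions", "compression time outside [0, duration]")
  }
  if (length(iss)) do.call(rbind, iss)
  else data.frame(severity = character(0), where = character(0),
                  message = character(0))
}

#' Time of recognition of the pulseless state
#'
#' The anchor for most timed checklist items: the time of the first
#' `pulse_check` event whose `pulse_result` is `"absent"`. Input event order
#' is irrelevant (the record is time-sorted on construction).
#'
#' @param record A `scenario_record`.
#' @return Time in seconds from scenario start, or `NA_real_` if the
#'   pulseless state was never recognised.
#' @export
recognition_time <- function(record) {
  ev <- record$events
  hit <- ev$action == "pulse_check" & !is.na(ev$pulse_result) &
    ev$pulse_result == "absent"
  if (!any(hit)) return(NA_real_)
  min(ev$t[hit])
}

# ---- serialization ---------------------------------------------------------

.config_to_list <- function(config) {
  unclass(config)
}

.config_from_list <- function(x) {
  scenario_config(
    patient_weight_kg = x$patient_weight_kg,
    duration_s = x$duration_s,
    rhythm = x$rhythm,
    required_reversible_causes = unlist(x$required_reversible_causes),
    allowed_cause_medications = unlist(x$allowed_cause_medications),
    thresholds = default_thresholds()[names(default_thresholds())] |>
      (\(d) { d[names(x$thresholds)] <- x$thresholds; d })()
  )
}

.fmt_num <- function(x) {
  # shortest decimal text that round-trips the double exactly
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- format(v, digits = 15, scientific = FALSE)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

.attrs_to_string <- function(row) {
  parts <- character(0)
  for (a in .attr_cols) {
    v <- row[[a]]
    if (!is.na(v)) {
      parts <- c(parts, paste0(a, "=", if (a %in% .num_attrs) .fmt_num(v) else v))
    }
  }
  paste(parts, collapse = ";")
}

.attrs_from_string <- function(s) {
  out <- stats::setNames(rep(list(NA), length(.attr_cols)), .attr_cols)
  if (is.na(s) || !nzchar(s)) return(out)
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1) stop("malformed attribute pair: '", kv, "'")
    k <- substr(kv, 1, eq - 1)
    v <- substr(kv, eq + 1, nchar(kv))
    if (!k %in% .attr_cols) stop("unknown attribute '", k, "'")
    out[[k]] <- if (k %in% .num_attrs) as.numeric(v) else v
  }
  out
}

#' Serialize a scenario record
#'
#' Writes a [scenario_record()] as CSV or JSON. The JSON layout is
#' `{team_id, group, config, events, compressions}` with events as
#' `{t, action, attributes}` objects. The CSV layout is a single table with
#' columns `team_id, group, t_seconds, action, attributes`
#' (semicolon-separated `key=value` pairs); compression records travel as
#' pseudo-events with action `chest_compression` and attributes `depth_cm`
#' and `release_residual_cm`, and the configuration rides in a
#' `# config: <json>` comment header. Both formats round-trip exactly
#' through [read_event_log()].
#'
#' @param record A valid `scenario_record`.
#' @param path Optional file path; when NULL the serialized text is returned.
#' @param format `"csv"` or `"json"`.
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_event_log <- function(record, path = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "scenario_record"))
  if (format == "json") {
    ev <- record$events
    events <- lapply(seq_len(nrow(ev)), function(i) {
      at <- list()
      for (a in .attr_cols) if (!is.na(ev[[a]][i])) at[[a]] <- ev[[a]][i]
      list(t = ev$t[i], action = ev$action[i], attributes = at)
    })
    cp <- record$compressions
    comps <- lapply(seq_len(nrow(cp)), function(i)
      list(t = cp$t[i], depth_cm = cp$depth_cm[i],
           release_residual_cm = cp$release_residual_cm[i]))
    obj <- list(team_id = record$team_id, group = record$group,
                config = .config_to_list(record$config),
                events = events, compressions = comps)
    txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                            null = "null")
  } else {
    header <- c(paste0("# log: ",
                       jsonlite::toJSON(list(team_id = record$team_id,
                                             group = record$group),
                                        auto_unbox = TRUE)),
                paste0("# config: ",
                       jsonlite::toJSON(.config_to_list(record$config),
                                        auto_unbox = TRUE, digits = NA)))
    ev <- record$events
    lines <- c(header, "team_id,group,t_seconds,action,attributes")
    row_line <- function(t, action, attrs) {
      sprintf("%s,%s,%s,%s,%s", record$team_id, record$group, .fmt_num(t),
              action, attrs)
    }
    for (i in seq_len(nrow(ev)))
      lines <- c(lines, row_line(ev$t[i], ev$action[i],
                                 .attrs_to_string(ev[i, ])))
    cp <- record$compressions
    for (i in seq_len(nrow(cp)))
      lines <- c(lines, row_line(cp$t[i], "chest_compression",
                                 sprintf("depth_cm=%s;release_residual_cm=%s",
                                         .fmt_num(cp$depth_cm[i]),
                                         .fmt_num(cp$release_residual_cm[i]))))
    txt <- paste(lines, collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = FALSE)
    return(invisible(txt))
  }
  txt
}

#' Read a scenario event log
#'
#' Parses a CSV or JSON event log (schema of [write_event_log()]) into a
#' [scenario_record()]. Events are re-sorted by time with a warning if the
#' source was out of order; rows failing validation with severity `"error"`
#' (for example an `administer_adrenaline` row lacking `dose_mg`) abort with
#' a message naming the offending line; unknown action kinds are preserved
#' and reported as warnings.
#'
#' @param source File path, or a character scalar holding the serialized
#'   text itself.
#' @param format `"csv"`, `"json"` or `"auto"` (sniffed from content).
#' @return A validated `scenario_record`.
#' @export
read_event_log <- function(source, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  txt <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  else paste(source, collapse = "\n")
  if (format == "auto")
    format <- if (grepl("^\\s*\\{", txt)) "json" else "csv"

  if (format == "json") {
    obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    evs <- lapply(obj$events, function(e) {
      row <- c(list(t = as.numeric(e$t), action = as.character(e$action)),
               e$attributes)
      as.data.frame(row, stringsAsFactors = FALSE)
    })
    ts <- vapply(obj$events, function(e) as.numeric(e$t), numeric(1))
    if (length(ts) > 1 && is.unsorted(ts))
      warning("events out of order in source; re-sorted by time")
    events <- if (length(evs)) as_events(do.call(.rbind_fill, evs)) else NULL
    comps <- if (length(obj$compressions))
      as_compressions(do.call(rbind, lapply(obj$compressions, as.data.frame)))
    else NULL
    rec <- scenario_record(obj$team_id, obj$group, events, comps,
                           .config_from_list(obj$config))
  } else {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    cfg_line <- grep("^# config:", lines, value = TRUE)
    config <- if (length(cfg_line))
      .config_from_list(jsonlite::fromJSON(sub("^# config: *", "", cfg_line[1]),
                                           simplifyVector = FALSE))
    else scenario_config()
    log_line <- grep("^# log:", lines, value = TRUE)
    team_id <- NULL; group <- NULL
    if (length(log_line)) {
      meta <- jsonlite::fromJSON(sub("^# log: *", "", log_line[1]))
      team_id <- meta$team_id; group <- meta$group
    }
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(body)) stop("empty CSV event log")
    header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    need <- c("team_id", "group", "t_seconds", "action", "attributes")
    if (!identical(header[seq_along(need)], need))
      stop("CSV header must be: ", paste(need, collapse = ","))
    rows <- body[-1]
    ev_rows <- list(); cp_rows <- list(); ts_seen <- numeric(0)
    for (li in seq_along(rows)) {
      # attributes field may contain no commas by construction
      parts <- strsplit(rows[li], ",", fixed = TRUE)[[1]]
      if (length(parts) < 4)
        stop(sprintf("malformed CSV row at line %d: '%s'", li + 1L, rows[li]))
      if (length(parts) == 4) parts <- c(parts, "")
      team_id <- parts[1]; group <- parts[2]
      t <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(t))
        stop(sprintf("malformed time in column t_seconds at line %d", li + 1L))
      if (parts[4] == "chest_compression") {
        kv <- .parse_generic_attrs(parts[5])
        if (is.null(kv[["depth_cm"]]) || is.null(kv[["release_residual_cm"]]))
          stop(sprintf("line %d: chest_compression row needs depth_cm and release_residual_cm",
                       li + 1L))
        cp_rows[[length(cp_rows) + 1L]] <-
          data.frame(t = t, depth_cm = as.numeric(kv[["depth_cm"]]),
                     release_residual_cm = as.numeric(kv[["release_residual_cm"]]))
      } else {
        attrs <- tryCatch(.attrs_from_string(parts[5]),
                          error = function(e)
                            stop(sprintf("line %d: %s", li + 1L, conditionMessage(e)),
                                 call. = FALSE))
        ts_seen <- c(ts_seen, t)
        row <- c(list(t = t, action = parts[4], line = li + 1L), attrs)
        ev_rows[[length(ev_rows) + 1L]] <- row
      }
    }
    if (length(ts_seen) > 1 && is.unsorted(ts_seen))
      warning("events out of order in source; re-sorted by time")
    events <- if (length(ev_rows)) {
      df <- do.call(.rbind_fill,
                    lapply(ev_rows, function(r)
                      as.data.frame(r[setdiff(names(r), "line")],
                                    stringsAsFactors = FALSE)))
      df
    } else NULL
    # per-line required-attribute errors before generic validation
    for (r in ev_rows) {
      req <- .required_attrs[[r$action]]
      for (a in req) if (is.null(r[[a]]) || is.na(r[[a]]))
        stop(sprintf("line %d (%s): missing required attribute '%s'",
                     r$line, r$action, a))
    }
    comps <- if (length(cp_rows)) do.call(rbind, cp_rows) else NULL
    rec <- scenario_record(team_id, group, events, comps, config)
  }
  iss <- validate_record(rec)
  if (any(iss$severity == "error")) {
    stop("invalid event log:\n  ",
         paste(iss$message[iss$severity == "error"], collapse = "\n  "))
  }
  for (m in iss$message[iss$severity == "warning"]) warning(m, call. = FALSE)
  rec
}

.parse_generic_attrs <- function(s) {
  kvs <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (kv in kvs) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq >= 1) out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}

# rbind data.frames with differing attribute columns
.rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  })
  do.call(rbind, dfs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
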