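# Clinical-Performance-Tool-style rubric engine. The validated asystole
# instrument has seven items totalling 0-13 (higher is better); its exact
# item wording and point split are not in the public domain, so the engine
# is config-driven and ships a documented approximation as the default
# rubric. Predicates are small declarative specs compiled against the
# scenario_record vocabulary.

.predicate_types <- c("recognized", "action_present", "action_within",
                      "adrenaline_correct", "all_of")

.compile_predicate <- function(p) {
  if (is.null(p$type)) stop("predicate missing 'type'")
  if (!p$type %in% .predicate_types)
    stop("unknown predicate primitive '", p$type, "'")
  if (p$type %in% c("action_present", "action_within") &&
      !p$action %in% action_kinds())
    stop("predicate references unknown action kind '", p$action, "'")
  switch(p$type,
    recognized = function(record) !is.na(recognition_time(record)),
    action_present = function(record)
      any(record$events$action == p$action),
    action_within = function(record) {
      t <- record$events$t[record$events$action == p$action]
      if (!length(t)) return(FALSE)
      anchor <- if (identical(p$anchor, "start")) 0 else recognition_time(record)
      if (is.na(anchor)) return(FALSE)
      min(t) - anchor <= p$window_s
    },
    adrenaline_correct = function(record) {
      ev <- record$events
      i <- which(ev$action == "administer_adrenaline")
      if (!length(i)) return(FALSE)
      row <- ev[i[1], ]
      th <- record$config$thresholds
      target <- 0.01 * record$config$patient_weight_kg
      !is.na(row$dose_mg) &&
        abs(row$dose_mg - target) / target < th$dose_tolerance &&
        !is.na(row$route) && row$route %in% c("IV", "IO")
    },
    all_of = {
      subs <- lapply(p$of, .compile_predicate)
      function(record) all(vapply(subs, function(f) f(record), logical(1)))
    })
}

#' Load and compile a scoring rubric
#'
#' A rubric is a named list (or YAML/JSON file) with `name`, `max_score`
#' and `items`; each item has `id`, `label`, `points_full`, a `predicate`,
#' and optionally `points_partial` with a `predicate_partial`. Predicate
#' primitives: `recognized` (pulseless state recognised),
#' `action_present` (`action`), `action_within` (`action`, `window_s`,
#' `anchor` = `"recognition"` or `"start"`), `adrenaline_correct`
#' (dose within tolerance and IV/IO route), `all_of` (`of` = list of
#' sub-predicates). Item points must sum to `max_score`.
#'
#' @param config A list, or the path of a YAML or JSON rubric file.
#' @return Object of class `cpt_rubric` with compiled predicates.
#' @export
load_rubric <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config), !is.null(config$items), !is.null(config$max_score))
  items <- lapply(config$items, function(it) {
    stopifnot(!is.null(it$id), !is.null(it$points_full), !is.null(it$predicate))
    if (!is.null(it$points_partial)) {
      if (it$points_partial >= it$points_full)
        stop("item '", it$id, "': points_partial must be below points_full")
      if (is.null(it$predicate_partial))
        stop("item '", it$id, "': points_partial without predicate_partial")
    }
    list(id = it$id,
         label = it$label %||% as.character(it$id),
         points_full = as.integer(it$points_full),
         points_partial = if (is.null(it$points_partial)) NA_integer_
                          else as.integer(it$points_partial),
         full = .compile_predicate(it$predicate),
         partial = if (is.null(it$predicate_partial)) NULL
                   else .compile_predicate(it$predicate_partial))
  })
  total <- sum(vapply(items, `[[`, integer(1), "points_full"))
  if (total != config$max_score)
    stop(sprintf("item points sum to %d but max_score is %d",
                 total, config$max_score))
  structure(list(name = config$name %||% "rubric",
                 items = items,
                 max_score = as.integer(config$max_score)),
            class = "cpt_rubric")
}

#' Default asystole rubric (7 items, 0-13)
#'
#' A documented approximation of the validated asystole scoring instrument:
#' the true item definitions are not publicly deposited, so this default
#' covers the same clinical ground — rhythm/pulselessness recognition,
#' timely CPR, bag-mask ventilation, EKG monitoring, vascular access,
#' adrenaline administration and correct adrenaline dosing — with a point
#' split totalling 13. Treat scores from it as rubric-engine output, not as
#' scores on the original validated instrument; the original can be loaded
#' via [load_rubric()] once transcribed.
#'
#' @return A compiled `cpt_rubric`.
#' @export
default_cpt_rubric <- function() {
  spec <- list(
    name = "asystole_default",
    max_score = 13,
    items = list(
      list(id = "recognition", label = "Pulseless state recognised by pulse check",
           points_full = 1,
           predicate = list(type = "recognized")),
      list(id = "cpr", label = "Chest compressions started promptly",
           points_full = 2, points_partial = 1,
           predicate = list(type = "action_within", action = "start_compressions",
                            window_s = 60, anchor = "recognition"),
           predicate_partial = list(type = "action_present",
                                    action = "start_compressions")),
      list(id = "ventilation", label = "Bag-mask ventilation started promptly",
           points_full = 2, points_partial = 1,
           predicate = list(type = "action_within", action = "start_bag_mask",
                            window_s = 60, anchor = "recognition"),
           predicate_partial = list(type = "action_present",
                                    action = "start_bag_mask")),
      list(id = "monitoring", label = "EKG monitoring established promptly",
           points_full = 2, points_partial = 1,
           predicate = list(type = "action_within", action = "start_ekg_monitor",
                            window_s = 60, anchor = "recognition"),
           predicate_partial = list(type = "action_present",
                                    action = "start_ekg_monitor")),
      list(id = "access", label = "Vascular (IV/IO) access established",
           points_full = 2, points_partial = 1,
           predicate = list(type = "action_present", action = "establish_iv_io"),
           predicate_partial = list(type = "action_present",
                                    action = "call_iv_io_access")),
      list(id = "adrenaline", label = "Adrenaline administered",
           points_full = 2, points_partial = 1,
           predicate = list(type = "action_present",
                            action = "administer_adrenaline"),
           predicate_partial = list(type = "action_present",
                                    action = "call_adrenaline")),
      list(id = "adrenaline_quality", label = "Adrenaline dose and route correct",
           points_full = 2,
           predicate = list(type = "adrenaline_correct"))
    ))
  load_rubric(spec)
}

#' Score a record on a rubric
#'
#' Each item is awarded `points_full` when its predicate holds, otherwise
#' `points_partial` when the partial predicate holds, otherwise 0. Scoring
#' is deterministic in the record and rubric.
#'
#' @param record A [scenario_record()].
#' @param rubric A compiled [load_rubric()] result; default
#'   [default_cpt_rubric()].
#' @return Object of class `cpt_score`: list with `team_id`, `items`
#'   (data.frame id, label, points), `total` and `max_score`.
#' @export
score_cpt <- function(record, rubric = default_cpt_rubric()) {
  stopifnot(inherits(record, "scenario_record"), inherits(rubric, "cpt_rubric"))
  pts <- vapply(rubric$items, function(it) {
    if (it$full(record)) return(it$points_full)
    if (!is.null(it$partial) && it$partial(record)) return(it$points_partial)
    0L
  }, integer(1))
  items <- data.frame(id = vapply(rubric$items, `[[`, character(1), "id"),
                      label = vapply(rubric$items, `[[`, character(1), "label"),
                      points = pts)
  structure(list(team_id = record$team_id, group = record$group,
                 items = items, total = sum(pts),
                 max_score = rubric$max_score),
            class = "cpt_score")
}

#' @export
print.cpt_score <- function(x, ...) {
  cat(sprintf("<cpt_score> team %s: %d/%d\n", x$team_id, x$total, x$max_score))
  invisible(x)
}
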